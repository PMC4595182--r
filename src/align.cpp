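#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>

using namespace Rcpp;

// Gotoh global alignment with affine gaps: a gap of length k scores
// gap_open + k * gap_extend. Three states: M (column is a substitution),
// Ix (column is a gap in b, i.e. a-char vs '-'), Iy (gap in a).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double subst(char x, char y, double match, double mismatch) {
  // N is unknown: it never matches anything, including another N
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

// Score-only DP with rolling rows: O(m) memory.
static double gotoh_score(const std::string &a, const std::string &b,
                          double match, double mismatch,
                          double go, double ge) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<double> M(m + 1), Ix(m + 1), Iy(m + 1);
  std::vector<double> Mp(m + 1), Ixp(m + 1), Iyp(m + 1);

  Mp[0] = 0.0; Ixp[0] = NEG_INF; Iyp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Ixp[j] = NEG_INF;
    Iyp[j] = go + ge * j;
  }
  for (int i = 1; i <= n; ++i) {
    M[0] = NEG_INF; Iy[0] = NEG_INF;
    Ix[0] = go + ge * i;
    for (int j = 1; j <= m; ++j) {
      double s = subst(a[i - 1], b[j - 1], match, mismatch);
      M[j] = s + std::max(Mp[j - 1], std::max(Ixp[j - 1], Iyp[j - 1]));
      Ix[j] = std::max(Mp[j] + go + ge,
                       std::max(Ixp[j] + ge, Iyp[j] + go + ge));
      Iy[j] = std::max(M[j - 1] + go + ge,
                       std::max(Iy[j - 1] + ge, Ix[j - 1] + go + ge));
    }
    std::swap(M, Mp); std::swap(Ix, Ixp); std::swap(Iy, Iyp);
  }
  return std::max(Mp[m], std::max(Ixp[m], Iyp[m]));
}

// Full DP with traceback; returns score and the number of alignment columns.
static void gotoh_align(const std::string &a, const std::string &b,
                        double match, double mismatch,
                        double go, double ge,
                        double &score_out, int &ncol_out) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), Ix((n + 1) * W, NEG_INF),
      Iy((n + 1) * W, NEG_INF);
  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) Iy[j] = go + ge * j;
  for (int i = 1; i <= n; ++i) Ix[i * W] = go + ge * i;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = subst(a[i - 1], b[j - 1], match, mismatch);
      int pd = (i - 1) * W + (j - 1), pu = (i - 1) * W + j,
          pl = i * W + (j - 1), cur = i * W + j;
      M[cur] = s + std::max(M[pd], std::max(Ix[pd], Iy[pd]));
      Ix[cur] = std::max(M[pu] + go + ge,
                         std::max(Ix[pu] + ge, Iy[pu] + go + ge));
      Iy[cur] = std::max(M[pl] + go + ge,
                         std::max(Iy[pl] + ge, Ix[pl] + go + ge));
    }
  }
  int i = n, j = m;
  int cur = i * W + j;
  int state;  // 0 = M, 1 = Ix, 2 = Iy
  double best = M[cur]; state = 0;
  if (Ix[cur] > best) { best = Ix[cur]; state = 1; }
  if (Iy[cur] > best) { best = Iy[cur]; state = 2; }
  score_out = best;

  int ncol = 0;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    ++ncol;
    if (state == 0) {
      double s = subst(a[i - 1], b[j - 1], match, mismatch);
      int pd = (i - 1) * W + (j - 1);
      double t = M[i * W + j] - s;
      if (std::abs(t - M[pd]) < eps) state = 0;
      else if (std::abs(t - Ix[pd]) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      int pu = (i - 1) * W + j;
      double t = Ix[i * W + j];
      if (std::abs(t - (Ix[pu] + ge)) < eps) state = 1;
      else if (std::abs(t - (M[pu] + go + ge)) < eps) state = 0;
      else state = 2;
      --i;
    } else {
      int pl = i * W + (j - 1);
      double t = Iy[i * W + j];
      if (std::abs(t - (Iy[pl] + ge)) < eps) state = 2;
      else if (std::abs(t - (M[pl] + go + ge)) < eps) state = 0;
      else state = 1;
      --j;
    }
  }
  ncol_out = ncol;
}

static std::string revcomp_cpp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

static std::string rotate_cpp(const std::string &s, int r) {
  if (r == 0) return s;
  return s.substr(r) + s.substr(0, r);
}

// Best global alignment of a against b, maximised over strand of b and all
// cyclic rotations of the (possibly reverse-complemented) b. Ties resolved
// forward-before-reverse, then smallest rotation offset.
// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b,
                    double match, double mismatch,
                    double gap_open, double gap_extend) {
  const int m = (int)b.size();
  double best = NEG_INF;
  int best_rot = 0, best_rev = 0;

  for (int rev = 0; rev <= 1; ++rev) {
    std::string bb = rev ? revcomp_cpp(b) : b;
    for (int r = 0; r < m; ++r) {
      std::string br = rotate_cpp(bb, r);
      double sc = gotoh_score(a, br, match, mismatch, gap_open, gap_extend);
      if (sc > best + 1e-12) {
        best = sc; best_rot = r; best_rev = rev;
      }
    }
  }
  std::string bwin = rotate_cpp(best_rev ? revcomp_cpp(b) : b, best_rot);
  double score_tb; int ncol;
  gotoh_align(a, bwin, match, mismatch, gap_open, gap_extend, score_tb, ncol);

  return List::create(
      _["raw_score"] = best,
      _["orientation"] = best_rev ? "reverse_complement" : "forward",
      _["rotation"] = best_rot,
      _["alignment_length"] = ncol);
}

// Pairwise normalised-score matrix over a vector of sequences (upper
// triangle computed, mirrored). Normalisation: raw / (match * min length),
// floored at 0.
// [[Rcpp::export]]
NumericMatrix score_matrix_cpp(CharacterVector seqs,
                               double match, double mismatch,
                               double gap_open, double gap_extend) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<std::string> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      const int m = (int)v[j].size();
      double best = NEG_INF;
      for (int rev = 0; rev <= 1; ++rev) {
        std::string bb = rev ? revcomp_cpp(v[j]) : v[j];
        for (int r = 0; r < m; ++r) {
          double sc = gotoh_score(v[i], rotate_cpp(bb, r), match, mismatch,
                                  gap_open, gap_extend);
          if (sc > best) best = sc;
        }
      }
      double denom = match * std::min(v[i].size(), v[j].size());
      double ns = denom > 0 ? best / denom : 0.0;
      if (ns < 0) ns = 0.0;
      if (ns > 1) ns = 1.0;
      out(i, j) = ns;
      out(j, i) = ns;
    }
  }
  return out;
}
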