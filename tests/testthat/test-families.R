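make_catalog <- function(consensuses) {
  n <- length(consensuses)
  tibble::tibble(
    contig = "c1",
    start = seq_len(n) * 1000L,
    end = seq_len(n) * 1000L + 400L,
    repeat_length = nchar(consensuses),
    n_repeats = 10L,
    consensus = consensuses)
}

test_that("related satellites form one family; random ones stay singletons", {
  set.seed(1)
  anc <- rand_seq(30)
  related <- c(anc, vapply(1:4, function(i) mutate_seq(anc, 0.07), character(1)))
  unrelated <- vapply(1:3, function(i) rand_seq(30), character(1))
  fam <- build_families(make_catalog(c(related, unrelated)))
  sizes <- sort(table(fam$family_id), decreasing = TRUE)
  expect_equal(as.integer(sizes), c(5L, 1L, 1L, 1L))
  # the family of five is the related block
  big <- as.integer(names(sizes)[1])
  expect_setequal(which(fam$family_id == big), 1:5)
})

test_that("rotations and reverse complements of one unit cluster together", {
  set.seed(2)
  u <- rand_seq(28)
  variants <- c(u, rotate_seq(u, 5), rotate_seq(u, 13),
                revcomp(u), rotate_seq(revcomp(u), 9))
  fam <- build_families(make_catalog(variants))
  expect_equal(length(unique(fam$family_id)), 1L)
})

test_that("threshold 1.0 splits off any mutated member", {
  set.seed(3)
  u <- rand_seq(30)
  mut <- u
  substr(mut, 10, 10) <- setdiff(bases, substr(u, 10, 10))[1]
  fam <- build_families(make_catalog(c(u, u, u, mut)), threshold = 1.0)
  expect_equal(sort(as.integer(table(fam$family_id))), c(1L, 3L))
  expect_equal(length(unique(fam$family_id[1:3])), 1L)
})

test_that("families partition the satellite set and ignore input order", {
  set.seed(4)
  anc <- replicate(3, rand_seq(25))
  cons <- c(vapply(rep(anc, each = 4), function(a) mutate_seq(a, 0.05),
                   character(1)),
            replicate(2, rand_seq(25)))
  cat1 <- make_catalog(cons)
  fam1 <- build_families(cat1)
  expect_equal(nrow(fam1), nrow(cat1))           # nothing dropped
  expect_false(anyNA(fam1$family_id))            # nothing unassigned

  perm <- sample(nrow(cat1))
  fam2 <- build_families(cat1[perm, ])
  # same partition after mapping back to original rows
  part1 <- split(seq_len(nrow(cat1)), fam1$family_id)
  part2 <- split(perm, fam2$family_id)
  norm <- function(p) unname(lapply(p[order(vapply(p, min, numeric(1)))], sort))
  expect_equal(norm(part1), norm(part2))
})

test_that("raising the threshold refines the partition", {
  set.seed(5)
  anc <- rand_seq(24)
  cons <- c(vapply(1:6, function(i) mutate_seq(anc, 0.08), character(1)),
            replicate(2, rand_seq(24)))
  catg <- make_catalog(cons)
  f_low <- build_families(catg, threshold = 0.6)$family_id
  f_high <- build_families(catg, threshold = 0.9)$family_id
  # every high-threshold cluster sits inside one low-threshold cluster
  for (cl in unique(f_high)) {
    expect_equal(length(unique(f_low[f_high == cl])), 1L)
  }
})

test_that("family names follow the Spp_Fam_rank_length_members convention", {
  # synthetic membership: one family of 213 (consensus 35 nt), one singleton
  sats <- tibble::tibble(
    contig = "I",
    start = c(seq_len(213) * 100L, 50000L),
    end = c(seq_len(213) * 100L + 50L, 50500L),
    repeat_length = c(rep(35L, 213), 17L),
    n_repeats = 10L,
    consensus = c(rep(strrep("ACGTACG", 5), 213), strrep("AC", 8)),
    family_id = c(rep(1L, 213), 2L),
    family_consensus = c(rep(strrep("ACGTACG", 5), 213), strrep("AC", 8)))
  nm <- name_families(sats, species_tag = "Cele")
  expect_equal(nm$families$family[1], "Cele_Fam_1_35_213")
  expect_equal(nm$families$family[2], "Cele_Fam_2_16_1")
  expect_equal(nm$satellites$family[1], "Cele_Fam_1_35_213")
})

test_that("equal-sized families rank by earliest genomic position", {
  sats <- tibble::tibble(
    contig = "I",
    start = c(5000L, 6000L, 1000L, 2000L),
    end = c(5100L, 6100L, 1100L, 2100L),
    repeat_length = 20L, n_repeats = 10L,
    consensus = "ACGTACGTACGTACGTACGT",
    family_id = c(1L, 1L, 2L, 2L),
    family_consensus = c("G", "G", "A", "A"))
  nm <- name_families(sats, "Tst")
  # family 2 starts earlier (1000 < 5000) so it takes rank 1
  expect_equal(nm$families$rank[nm$families$consensus == "A"], 1L)
  expect_equal(nm$families$rank[nm$families$consensus == "G"], 2L)
})

test_that("family size classes partition the family list", {
  fams <- tibble::tibble(n_members = c(213L, 5L, 2L, 1L, 1L))
  tab <- family_size_table(fams)
  expect_equal(tab$total, 5L)
  expect_equal(tab$gt9, 1L)
  expect_equal(tab$from3to9, 1L)
  expect_equal(tab$two, 1L)
  expect_equal(tab$one, 2L)
  expect_equal(tab$gt9 + tab$from3to9 + tab$two + tab$one, tab$total)

  all_single <- tibble::tibble(n_members = rep(1L, 7))
  tab2 <- family_size_table(all_single)
  expect_equal(tab2$total, 7L)
  expect_equal(tab2$one, 7L)
})

test_that("cross-species comparison links shared consensuses into super-families", {
  set.seed(6)
  shared <- rand_seq(40)
  nm <- simulate_null(40, n_pairs = 500, seed = 7)
  mk_fams <- function(spp, consensuses) {
    tibble::tibble(
      family = sprintf("%s_Fam_%d_%d_1", spp, seq_along(consensuses),
                       nchar(consensuses)),
      rank = seq_along(consensuses), consensus = consensuses,
      consensus_length = nchar(consensuses),
      n_members = 1L, contig = "c1",
      first_start = seq_along(consensuses) * 100L, species = spp)
  }
  sets <- list(
    A = mk_fams("A", c(shared, rand_seq(40))),
    B = mk_fams("B", c(mutate_seq(shared, 0.03), rand_seq(40))),
    C = mk_fams("C", c(rotate_seq(shared, 11), rand_seq(40))),
    D = mk_fams("D", c(revcomp(shared), rand_seq(40))))
  res <- compare_species(sets, nm, alpha = 0.01)
  spans <- res$superfamilies
  shared_rows <- spans[grepl("_Fam_1_", spans$family), ]
  expect_equal(length(unique(shared_rows$superfamily_id)), 1L)
  expect_equal(unique(shared_rows$n_species), 4L)
  # the random families stay species-specific
  rand_rows <- spans[grepl("_Fam_2_", spans$family), ]
  expect_true(all(rand_rows$n_species == 1L))
  expect_true("A+B+C+D" %in% res$venn$species_set)
})

test_that("disjoint random consensuses give 100% species-specific families", {
  set.seed(8)
  nm <- simulate_null(30, n_pairs = 500, seed = 9)
  mk <- function(spp) tibble::tibble(
    family = sprintf("%s_Fam_%d_30_1", spp, 1:3), rank = 1:3,
    consensus = replicate(3, rand_seq(30)), consensus_length = 30L,
    n_members = 1L, contig = "c1", first_start = 1:3 * 100L, species = spp)
  res <- compare_species(list(X = mk("X"), Y = mk("Y")), nm, alpha = 0.01)
  expect_true(all(res$species_specific$frac_specific == 1))
})
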