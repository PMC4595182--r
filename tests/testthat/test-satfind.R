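test_that("random recurrence expectation follows N * (4^-L)^n", {
  expect_equal(random_expectation(1000, 10, 1), 1000 * 4^-10)
  expect_equal(random_expectation(0, 10, 9), 0)
  # log-space evaluation agrees with direct double arithmetic deep in the tail
  expect_equal(random_expectation(2000, 10, 9), 2000 * (4^-10)^9,
               tolerance = 1e-12)
})

test_that("equal-length expectation is choose(n,k) * L^-(k-1)", {
  expect_equal(equal_length_expectation(7, 1, 500), 7)   # C(n,1) * L^0
  expect_equal(equal_length_expectation(10, 3, 2000), 120 / 2000^2)
  expect_equal(equal_length_expectation(2, 2, 10), 0.1)
})

test_that("seed clustering finds tandem 17-mers and honours the count threshold", {
  set.seed(42)
  unit <- rand_seq(17)
  while (minimal_period(unit) != 17) unit <- rand_seq(17)
  bg1 <- rand_seq(1000); bg2 <- rand_seq(1000)

  seq10 <- paste0(bg1, strrep(unit, 10), bg2)
  cand <- seed_clusters(seq10)
  expect_equal(nrow(cand), 1L)
  expect_lte(cand$start, 1000 + 17)
  expect_gte(cand$end, 1000 + 10 * 17 - 17)

  seq9 <- paste0(bg1, strrep(unit, 9), bg2)
  expect_equal(nrow(seed_clusters(seq9)), 0L)
})

test_that("internally repetitive decamers are never seeds", {
  # 50 copies of AC: the only abundant decamers have minimal period 2
  seq <- paste0(rand_seq(500), strrep("AC", 50), rand_seq(500))
  set.seed(7)
  expect_equal(nrow(seed_clusters(seq)), 0L)
})

test_that("extension recovers copies outside the seeding window and stops at big gaps", {
  set.seed(11)
  unit <- rand_seq(100)
  arr20 <- strrep(unit, 20)  # 2000 bp; no single 2 kb window holds all copies
  seq <- paste0(rand_seq(3000), arr20, rand_seq(3000))
  sats <- find_satellites(genome(c(c1 = seq)), consensus = FALSE)
  expect_equal(nrow(sats), 1L)
  expect_equal(sats$start, 3000L)
  expect_equal(sats$end, 3000L + 2000L)
  expect_equal(sats$n_repeats, 20L)

  # same unit in two arrays separated by more than max_gap: two satellites
  seq2 <- paste0(rand_seq(1000), strrep(unit, 12), rand_seq(2500),
                 strrep(unit, 12), rand_seq(1000))
  sats2 <- find_satellites(genome(c(c1 = seq2)), consensus = FALSE)
  expect_equal(nrow(sats2), 2L)
})

test_that("segmentation cuts at seed occurrences and units re-concatenate", {
  set.seed(13)
  unit <- rand_seq(17)
  while (minimal_period(unit) != 17) unit <- rand_seq(17)
  seq <- paste0(rand_seq(800), strrep(unit, 20), rand_seq(800))
  occ <- 800L + (0:19) * 17L
  segs <- segment_repeats(seq, occ, 10L)
  expect_length(segs, 1L)
  seg <- segs[[1]]
  expect_equal(seg$repeat_length, 17L)
  expect_equal(length(seg$units), 20L)
  expect_true(all(seg$units == unit))
  expect_equal(paste(seg$units, collapse = ""),
               substr(seq, seg$start + 1, seg$end))
})

test_that("alternating one-base indels keep the modal length and >= 50% regularity", {
  set.seed(17)
  u17 <- rand_seq(17)
  while (minimal_period(u17) != 17) u17 <- rand_seq(17)
  u18 <- paste0(u17, "A")  # insertion after the unit
  arr <- strrep(paste0(u17, u18), 10)  # 20 copies alternating 17/18
  seq <- paste0(rand_seq(500), arr, rand_seq(500))
  sats <- find_satellites(genome(c(c1 = seq)), consensus = FALSE)
  expect_equal(nrow(sats), 1L)
  expect_equal(sats$repeat_length, 17L)
  lens <- nchar(sats$units[[1]])
  expect_gte(mean(lens == 17L), 0.45)
})

test_that("regularity filter is inclusive at the 30% boundary", {
  u <- function(n) vapply(n, rand_seq, character(1))
  set.seed(19)
  units_pass <- u(c(17, 17, 17, 11, 12, 13, 14, 15, 16, 19))
  expect_true(regularity_filter(units_pass))       # 3/10 = 0.30 exactly
  units_fail <- u(c(17, 17, 11, 12, 13, 14, 15, 16, 19, 20))
  expect_false(regularity_filter(units_fail))      # 0.20
  units_distinct <- u(11:20)
  expect_false(regularity_filter(units_distinct))  # all distinct
})

test_that("five exact planted arrays are recovered with exact boundaries", {
  sim <- standard_fixture(seed = 1)
  sats <- find_satellites(sim$genome, consensus = FALSE)
  m <- detection_metrics(sats, sim$truth, slack_units = 1)
  expect_equal(m$recalled, 5L)
  expect_equal(m$true_positives, m$n_detected)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
})

test_that("pure random sequence yields no satellites", {
  set.seed(23)
  g <- genome(c(c1 = rand_seq(1e5, prob = c(0.3, 0.2, 0.2, 0.3))))
  expect_equal(nrow(find_satellites(g, consensus = FALSE)), 0L)
})

test_that("repeats above the 200 nt cap are not reported", {
  set.seed(29)
  unit <- rand_seq(205)
  seq <- paste0(rand_seq(2000), strrep(unit, 15), rand_seq(2000))
  expect_equal(nrow(find_satellites(genome(c(c1 = seq)), consensus = FALSE)), 0L)
})

test_that("unit boundaries conserve the genomic substring on every satellite", {
  sim <- standard_fixture(seed = 3, per_base_mutation = 0.03)
  sats <- find_satellites(sim$genome, consensus = FALSE)
  expect_gt(nrow(sats), 0L)
  for (i in seq_len(nrow(sats))) {
    expect_equal(paste(sats$units[[i]], collapse = ""),
                 substr(sim$genome[[sats$contig[i]]],
                        sats$start[i] + 1, sats$end[i]))
  }
})

test_that("detection is invariant to contig order and to N-run prefixes", {
  set.seed(31)
  unitA <- rand_seq(20); unitB <- rand_seq(30)
  seqA <- paste0(rand_seq(1000), strrep(unitA, 12), rand_seq(1000))
  seqB <- paste0(rand_seq(1000), strrep(unitB, 12), rand_seq(1000))

  s1 <- find_satellites(genome(c(cA = seqA, cB = seqB)), consensus = FALSE)
  s2 <- find_satellites(genome(c(cB = seqB, cA = seqA)), consensus = FALSE)
  cols <- c("contig", "start", "end", "repeat_length", "n_repeats")
  expect_equal(as.data.frame(s1[order(s1$contig), cols]),
               as.data.frame(s2[order(s2$contig), cols]),
               ignore_attr = TRUE)

  shifted <- find_satellites(genome(c(cA = paste0(strrep("N", 500), seqA))),
                             consensus = FALSE)
  plain <- find_satellites(genome(c(cA = seqA)), consensus = FALSE)
  expect_equal(shifted$start, plain$start + 500L)
  expect_equal(shifted$end, plain$end + 500L)
})
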