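make_track <- function(contig, pos, value) {
  trk <- tibble::tibble(contig = contig, pos = as.integer(pos), value = value)
  class(trk) <- c("satkit_track", class(trk))
  trk
}

one_sat <- function(start, end, contig = "c1", repeat_length = 20L) {
  tibble::tibble(contig = contig, start = as.integer(start),
                 end = as.integer(end), repeat_length = repeat_length,
                 n_repeats = 10L, consensus = "ACGT")
}

test_that("satellite affinity is the mean antilog over covered positions", {
  trk <- make_track("c1", 0:2, c(0, 0, 0))
  sc <- score_satellites(one_sat(0, 3), trk, log_base = 2)
  expect_equal(sc$mean_affinity, 1.0)        # antilog of 0

  trk <- make_track("c1", 0:2, c(1, 1, 1))
  expect_equal(score_satellites(one_sat(0, 3), trk, 2)$mean_affinity, 2.0)

  trk <- make_track("c1", c(0, 1), c(0, 2))
  expect_equal(score_satellites(one_sat(0, 2), trk, 2)$mean_affinity, 2.5)

  # uncovered positions are excluded, not imputed
  trk <- make_track("c1", c(0, 10), c(2, 2))
  sc <- score_satellites(one_sat(0, 20), trk, 2)
  expect_equal(sc$mean_affinity, 4)
  expect_equal(sc$n_covered, 2L)

  # zero coverage yields NA
  sc <- score_satellites(one_sat(100, 120), trk, 2)
  expect_true(is.na(sc$mean_affinity))
})

test_that("scoring is invariant to interval splitting with coverage weights", {
  set.seed(1)
  trk <- make_track("c1", 0:99, rnorm(100))
  whole <- score_satellites(one_sat(0, 100), trk, 2)
  left <- score_satellites(one_sat(0, 37), trk, 2)
  right <- score_satellites(one_sat(37, 100), trk, 2)
  weighted <- (left$mean_affinity * left$n_covered +
                 right$mean_affinity * right$n_covered) /
    (left$n_covered + right$n_covered)
  expect_equal(whole$mean_affinity, weighted)
})

test_that("median split classifies strictly above the median as high", {
  sc <- one_sat(0, 10)[rep(1, 2), ]
  sc$mean_affinity <- c(0.5, 1.5)
  ms <- median_split(sc)
  expect_equal(ms$median, 1.0)
  expect_equal(sort(ms$satellites$affinity_class), c("high", "low"))

  # odd count: the median element itself is low
  sc3 <- one_sat(0, 10)[rep(1, 3), ]
  sc3$mean_affinity <- c(0.5, 1.0, 1.5)
  ms3 <- median_split(sc3)
  expect_equal(ms3$satellites$affinity_class, c("low", "low", "high"))

  # all-tie input is flagged degenerate
  sc4 <- one_sat(0, 10)[rep(1, 4), ]
  sc4$mean_affinity <- rep(2, 4)
  expect_warning(ms4 <- median_split(sc4), "degenerate")
  expect_true(ms4$degenerate)
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  mk <- function(a, b, c, d) {
    s <- one_sat(0, 10)[rep(1, a + b + c + d), ]
    len <- c(rep(3000L, a + b), rep(500L, c + d))
    s$end <- s$start + len
    s$repeat_length <- c(rep(170L, a + b), rep(20L, c + d))
    s$affinity_class <- c(rep("high", a), rep("low", b),
                          rep("high", c), rep("low", d))
    s
  }
  r <- enrichment_test(mk(10, 0, 0, 10))
  expect_equal(r$table, matrix(c(10, 0, 0, 10), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(r$p_one_sided, 1 / choose(20, 10))
  expect_equal(r$p_one_sided, oracle_fisher_one_sided(r$table))

  r2 <- enrichment_test(mk(5, 5, 5, 5))
  expect_gt(r2$p_one_sided, 0.5)

  # balanced sample of tables with margins <= 40
  set.seed(2)
  for (i in 1:25) {
    a <- sample(0:10, 1); b <- sample(0:10, 1)
    c <- sample(0:10, 1); d <- sample(0:10, 1)
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    r <- enrichment_test(mk(a, b, c, d))
    expect_equal(r$p_one_sided, oracle_fisher_one_sided(r$table),
                 tolerance = 1e-12)
  }
})

test_that("an empty predicate selection is an error", {
  s <- one_sat(0, 500)[rep(1, 4), ]   # all short: predicate selects nothing
  s$affinity_class <- c("high", "low", "high", "low")
  expect_error(enrichment_test(s), "selects nothing")
})

test_that("position overlap counting is half-open", {
  sats <- one_sat(100, 200)
  pos <- tibble::tibble(contig = "c1", pos = c(100L, 200L, 150L, 50L))
  expect_equal(count_positions_within(sats, pos), 2L)  # 100 and 150 only
  pos2 <- tibble::tibble(contig = "c1", pos = c(10L, 150L, 300L))
  expect_equal(count_positions_within(sats, pos2), 1L)
  # wrong contig never counts
  pos3 <- tibble::tibble(contig = "c2", pos = 150L)
  expect_equal(count_positions_within(sats, pos3), 0L)
})
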