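test_that("callable mask counts strict in-range bases per window", {
  # all bases exactly at the mean -> strictly inside (mean/3, 2.5*mean)
  tr <- depth_track(region("1", 1, 3e4), rep(30, 3e4))
  cm <- callable_mask(tr, 30, 1e4)
  expect_equal(cm$callable, rep(1e4, 3))

  # all-zero depth -> nothing callable
  tr0 <- depth_track(region("1", 1, 2e4), rep(0, 2e4))
  expect_equal(callable_mask(tr0, 30, 1e4)$callable, c(0, 0))

  # boundary depths are excluded (strict inequalities)
  trb <- depth_track(region("1", 1, 4), c(10, 11, 74, 75))  # mean_cov 30
  expect_equal(callable_mask(trb, 30, 10)$callable, 2)

  # random track vs per-base brute force, track not starting at base 1
  set.seed(3)
  d <- sample(0:100, 25000, replace = TRUE)
  trr <- depth_track(region("2", 5001, 30000), d)
  got <- callable_mask(trr, 36, 1e3)
  expect_equal(got$callable, oracle_callable(d, 5001, 1e3, 36))
  expect_error(callable_mask(trr, 36, 0), "positive")
})

test_that("windowed heterozygosity arithmetic and the 60% exclusion rule", {
  p <- pipeline_params()
  mask <- data.table::data.table(chrom = "1",
                                 start = c(1, 1e6 + 1, 2e6 + 1),
                                 end = c(1e6, 2e6, 3e6),
                                 window_bp = 1e6,
                                 callable = c(1e6, 8e5, 5e5))
  set.seed(1)
  sites <- data.table::data.table(
    chrom = "1", pos = c(sample(1:1e6, 100), sample((1e6 + 1):2e6, 50),
                         sample((2e6 + 1):3e6, 10)))
  hw <- window_heterozygosity(sites, mask, p)
  expect_equal(hw$het, c(1e-4, 6.25e-5, 2e-5))
  expect_identical(hw$excluded, c(FALSE, FALSE, TRUE))  # 50% < 60%
  # genome mean over non-excluded windows, callable-weighted
  expect_equal(genome_mean_het(hw), 150 / 1.8e6)
})

test_that("call_roh trivial limits", {
  # all-zero heterozygosity -> one segment spanning each chromosome
  hw0 <- rbind(make_hw(rep(0, 20), genome_mean = 1e-3),
               make_hw(rep(0, 10), chrom = "2", genome_mean = 1e-3))
  data.table::setattr(hw0, "genome_mean_het", 1e-3)
  data.table::setattr(hw0, "class", unique(c("het_windows", class(hw0))))
  segs <- call_roh(hw0, genome_mean = 1e-3)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$start, c(1, 1))
  expect_equal(segs$end, c(2e5, 1e5))
  expect_true(all(segs$mean_het == 0))

  # every window at the genome mean -> nothing below the ceiling
  hw1 <- make_hw(rep(10, 30))  # het 1e-3 everywhere, mean 1e-3
  expect_equal(nrow(call_roh(hw1)), 0)

  # excluded windows break runs
  hw2 <- make_hw(rep(0, 30), excluded = replace(rep(FALSE, 30), 15, TRUE),
                 genome_mean = 1e-3)
  segs2 <- call_roh(hw2, genome_mean = 1e-3)
  expect_equal(nrow(segs2), 2)
  expect_equal(segs2$start, c(1, 15e4 + 1))
})

test_that("relaxed-peak merge: 10x spike merges, 15x spike splits", {
  gm <- 1e-3  # genome mean het; ceiling = 0.25 * gm
  spike <- function(mult) {
    n_het <- rep(0, 50)
    n_het[25] <- mult * gm * 1e4   # window het = mult * gm
    make_hw(n_het, genome_mean = gm)
  }
  # merged span mean = 10 * gm / 50 = 0.2 * gm < 0.25 * gm -> one segment
  segs10 <- call_roh(spike(10), genome_mean = gm)
  expect_equal(nrow(segs10), 1)
  expect_equal(segs10$n_windows, 50)
  expect_equal(segs10$mean_het, 10 * gm * 1e4 / (50 * 1e4))
  expect_lt(segs10$mean_het, 0.25 * gm)

  # 15x: merged mean would be 0.3 * gm >= ceiling -> two flanking segments
  segs15 <- call_roh(spike(15), genome_mean = gm)
  expect_equal(nrow(segs15), 2)
  expect_equal(segs15$n_windows, c(24, 25))
  expect_equal(segs15$start, c(1, 25e4 + 1))
})

test_that("multiple peaks are bridged when the whole span stays admissible", {
  gm <- 1e-3
  # [0 x10] peak9 [0 x10] peak2 [0 x30]: bridging one peak alone is easy;
  # the full span carries (9+2)gm/52 ~ 0.21gm < 0.25gm, so the maximal
  # segment covers everything
  n_het <- c(rep(0, 10), 9 * gm * 1e4, rep(0, 10), 2 * gm * 1e4, rep(0, 30))
  segs <- call_roh(make_hw(n_het, genome_mean = gm), genome_mean = gm)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_windows, 52)
  expect_lt(segs$mean_het, 0.25 * gm)

  # a span that would cross an inadmissible peak is split at the peak
  n_het2 <- c(rep(0, 5), 30 * gm * 1e4, rep(0, 5))
  segs2 <- call_roh(make_hw(n_het2, genome_mean = gm), genome_mean = gm)
  expect_equal(nrow(segs2), 2)
  expect_equal(segs2$n_windows, c(5, 5))
})

test_that("emitted segments always sit strictly below the ceiling", {
  set.seed(44)
  p <- pipeline_params()
  for (rep in 1:50) {
    n <- 40
    n_het <- rpois(n, sample(c(0.2, 2, 10), n, replace = TRUE))
    hw <- make_hw(n_het)
    gm <- genome_mean_het(hw)
    if (!is.finite(gm) || gm <= 0) next
    segs <- call_roh(hw)
    if (nrow(segs))
      expect_true(all(segs$mean_het < p$roh_het_ceiling_factor * gm))
    # disjoint and sorted
    if (nrow(segs) > 1)
      expect_true(all(segs$start[-1] > segs$end[-nrow(segs)]))
  }
})

test_that("scaling heterozygosity down never shrinks total ROH length", {
  set.seed(91)
  gm <- 1e-3
  viol <- 0L
  for (rep in 1:1000) {
    n <- 30
    n_het <- rpois(n, sample(c(0.1, 1, 5, 12), n, replace = TRUE))
    total <- function(scale) {
      hw <- make_hw(n_het * scale, genome_mean = gm)
      segs <- call_roh(hw, genome_mean = gm)
      if (nrow(segs)) sum(segs$length) else 0
    }
    c_scale <- runif(1, 0.1, 0.99)
    if (total(c_scale) < total(1)) viol <- viol + 1L
  }
  expect_equal(viol, 0L)
})

test_that("ROH summary: F_ROH over flagged-autosome length, strict long tally", {
  p <- pipeline_params()  # L = 2,682,350,267
  segs <- data.table::data.table(
    chrom = "1", start = c(1, 2e6, 4e6),
    end = c(150000, 2e6 + 90000 - 1, 4e6 + 2.5e6 - 1))
  s <- summarize_roh(segs, p)
  # 90 kb segment is below the 100 kb floor; 2.5 Mb is the only long one
  expect_equal(s$froh, (150000 + 2500000) / 2682350267)
  expect_equal(s$n_long, 1)
  expect_equal(s$n_segments, 3)
  expect_equal(s$total_roh_bp, 150000 + 90000 + 2500000)

  s0 <- summarize_roh(segs[0], p)
  expect_equal(s0$froh, 0)
  expect_equal(s0$n_long, 0)

  # one segment covering the whole denominator -> F_ROH = 1
  p2 <- pipeline_params(autosome_length_L = 5e6)
  s1 <- summarize_roh(data.table::data.table(chrom = "1", start = 1, end = 5e6), p2)
  expect_equal(s1$froh, 1)

  # exactly 2 Mb is not "longer than 2 Mb"
  s2 <- summarize_roh(data.table::data.table(chrom = "1", start = 1, end = 2e6), p)
  expect_equal(s2$n_long, 0)
})
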