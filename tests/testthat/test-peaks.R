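test_that("identical chip and control tracks produce zero peaks", {
  cts <- list(chr1 = c(5L, 80L, 3L, 200L, 7L), chr2 = c(0L, 1L, 50L, 2L, 9L))
  ps <- call_peaks(manual_track(cts), manual_track(cts))
  expect_equal(nrow(ps$peaks), 0L)
})

test_that("the single-bin p-value matches direct Poisson pmf summation", {
  # equal libraries and a flat control: lambda = (2 + 0.5) * 1 = 2.5 in every
  # bin, and the global background floor coincides with the local rate
  chip <- manual_track(list(chr1 = c(20L, rep(0L, 9))))
  ctrl <- manual_track(list(chr1 = rep(2L, 10)))
  expect_equal(chip$library_size, ctrl$library_size)
  ps <- call_peaks(chip, ctrl, p_cutoff = 1e-3, pseudocount = 0.5)
  expect_equal(nrow(ps$peaks), 1L)
  expect_equal(ps$peaks$p_value, pois_tail_oracle(20L, 2.5), tolerance = 1e-12)
  expect_lt(ps$peaks$p_value, 1e-3)
  expect_equal(ps$peaks$max_enrichment, 20 / 2.5)
})

test_that("per-bin p-values match the Poisson tail oracle to 1e-12 relative", {
  set.seed(61)
  lam <- runif(1000, 0.1, 50)
  cnt <- rpois(1000, lam) + sample(0:30, 1000, replace = TRUE)
  mine <- poisson_tail_p(cnt, lam)
  oracle <- vapply(seq_len(1000), function(i) pois_tail_oracle(cnt[i], lam[i]), numeric(1))
  expect_lt(max(abs(mine - oracle) / oracle), 1e-12)
})

test_that("significance is monotone in the cutoff and in the chip count", {
  set.seed(67)
  chip <- manual_track(list(chr1 = as.integer(rpois(500, 5) + rbinom(500, 30, 0.05))))
  ctrl <- manual_track(list(chr1 = as.integer(rpois(500, 5))))
  ctrl$library_size <- chip$library_size
  n_at <- vapply(c(1e-5, 1e-4, 1e-3, 1e-2), function(pc) {
    nrow(call_peaks(chip, ctrl, p_cutoff = pc)$peaks)
  }, numeric(1))
  expect_true(all(diff(n_at) >= 0))

  base <- call_peaks(chip, ctrl, p_cutoff = 1e-3)
  sig_bin <- which.max(chip$counts$chr1 / (ctrl$counts$chr1 + 0.5))
  boosted <- chip
  boosted$counts$chr1[sig_bin] <- boosted$counts$chr1[sig_bin] + 10L
  more <- call_peaks(boosted, ctrl, p_cutoff = 1e-3)
  covers <- function(ps, pos) {
    any(ps$peaks$start <= pos & pos < ps$peaks$end)
  }
  pos <- (sig_bin - 1L) * 200L
  if (covers(base, pos)) expect_true(covers(more, pos))
})

test_that("bridged gaps merge peaks while larger gaps split them", {
  v <- rep(2L, 30)
  v[c(10, 12)] <- 60L # gap of one non-significant bin
  v[c(20, 23)] <- 60L # gap of two
  chip <- manual_track(list(chr1 = v))
  ctrl <- manual_track(list(chr1 = rep(2L, 30)))
  ctrl$library_size <- chip$library_size
  ps <- call_peaks(chip, ctrl, merge_gap_bins = 1L)
  expect_equal(nrow(ps$peaks), 3L)
  expect_equal(ps$peaks$start, c(9L, 19L, 22L) * 200L)
  expect_equal(ps$peaks$end, c(12L, 20L, 23L) * 200L)
  ps0 <- call_peaks(chip, ctrl, merge_gap_bins = 0L)
  expect_equal(nrow(ps0$peaks), 4L)
})

test_that("track mismatches and empty controls are rejected", {
  chip <- manual_track(list(chr1 = rep(2L, 10)))
  ctrl_bad <- manual_track(list(chr1 = rep(2L, 8)))
  expect_error(call_peaks(chip, ctrl_bad), "binning")
  ctrl_other <- manual_track(list(chr1 = rep(2L, 10)), bin_size = 100L)
  expect_error(call_peaks(chip, ctrl_other), "binning")
  ctrl_zero <- manual_track(list(chr1 = rep(0L, 10)), library_size = 0L)
  expect_error(call_peaks(chip, ctrl_zero), "control library")
  ctrl_zero$library_size <- 10L
  expect_error(call_peaks(chip, ctrl_zero, pseudocount = 0), "pseudocount")
})

test_that("peak labels follow the midpoint and half-open boundary convention", {
  g <- small_genome(n_chrom = 1L) # tract [0,600), subtelomere [600, 5600)
  mk <- function(start, end) {
    manual_peaks("chr1", start, end, g$length)
  }
  inside_tract <- classify_and_filter(mk(100L, 400L), g)
  expect_equal(inside_tract$peaks$label, "telomeric")
  expect_equal(inside_tract$n_nontelomeric, 0L)
  # midpoint exactly on the tract/subtelomere boundary belongs to the subtelomere
  boundary <- classify_and_filter(mk(400L, 800L), g)
  expect_equal((400L + 800L) %/% 2L, 600L)
  expect_equal(boundary$peaks$label, "subtelomeric")
  interior <- classify_and_filter(mk(30000L, 30400L), g)
  expect_equal(interior$peaks$label, "interstitial")
  expect_equal(interior$n_nontelomeric, 1L)
  right_tract <- classify_and_filter(mk(59500L, 59900L), g)
  expect_equal(right_tract$peaks$label, "telomeric")
  stray <- manual_peaks("chrX", 10L, 100L, c(chrX = 1000))
  expect_error(classify_and_filter(stray, g), "unannotated")
})

test_that("peak-set overlap uses the 1-bp intersection convention", {
  lens <- c(chr1 = 10000)
  A <- manual_peaks("chr1", c(0L, 500L), c(100L, 600L), lens)
  B <- manual_peaks("chr1", c(99L, 5000L), c(200L, 5100L), lens)
  expect_equal(overlap_sets(A, A)$fraction_A_in_B, 1)
  o <- overlap_sets(A, B)
  expect_equal(o$n_shared, 1L) # 1-bp intersection at [99,100) counts
  expect_equal(o$fraction_A_in_B, 0.5)
  C <- manual_peaks("chr1", 9000L, 9100L, lens)
  expect_equal(overlap_sets(A, C)$n_shared, 0L)
  # adjacency (zero overlap) does not count
  D <- manual_peaks("chr1", 100L, 200L, lens)
  expect_equal(overlap_sets(manual_peaks("chr1", 0L, 100L, lens), D)$n_shared, 0L)
})

test_that("peak-count fold changes reproduce the printed-count arithmetic", {
  tab <- peak_fold_change(c(G0 = 147, G1 = 894, G3 = 2266), reference = "G0")
  expect_equal(tab$fold, c(1, 6.08, 15.41))
  expect_equal(tab$fold_rounded, c(1L, 6L, 15L))
  eq <- peak_fold_change(c(a = 50, b = 50))
  expect_equal(eq$fold[2], 1)
  expect_error(peak_fold_change(c(a = 0, b = 5)), "positive")
  expect_error(peak_fold_change(c(10, 20)), "named")
})
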