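test_that("uniform peaks give a flat density profile", {
  g <- build_genome(seed = 71L) # 3 x 1 Mb
  res <- lapply(1:10, function(s) {
    pos <- withr::with_seed(500 + s, {
      data.frame(
        chrom = sample(g$chrom, 10000, replace = TRUE),
        start = sample.int(1e6 - 200L, 10000, replace = TRUE) - 1L
      )
    })
    ps <- manual_peaks(pos$chrom, pos$start, pos$start + 200L, g$length)
    prof <- distance_profile(ps, g, n_bins = 20L)
    d <- prof$density[prof$available_bp > 0]
    gof <- stats::chisq.test(
      prof$n_peaks_per_bin,
      p = prof$available_bp / sum(prof$available_bp)
    )$p.value
    list(
      ratio = max(d) / min(d), gof = gof,
      trend = gradient_stats(prof)$trend_corr
    )
  })
  flat <- vapply(res, function(r) r$ratio <= 1.3 && r$gof > 0.001, logical(1))
  expect_gte(sum(flat), 9L)
  # no systematic trend across the ensemble: under flatness the per-seed rank
  # correlation is a random permutation statistic (sd ~ 0.23), so the bound
  # belongs on the 10-seed mean (sd ~ 0.07)
  expect_lte(abs(mean(vapply(res, `[[`, numeric(1), "trend"))), 0.25)
})

test_that("peaks hugging the ends land entirely in the first stratum", {
  g <- small_genome()
  ps <- manual_peaks(
    rep("chr1", 3), c(700L, 900L, 58800L), c(800L, 1000L, 58900L), g$length
  )
  prof <- distance_profile(ps, g, n_bins = 20L)
  expect_equal(prof$n_peaks_per_bin[1], 3L)
  expect_equal(sum(prof$n_peaks_per_bin), 3L)
})

test_that("available bp per stratum matches exhaustive enumeration", {
  for (len in c(100L, 101L)) {
    g <- small_genome(n_chrom = 1L)
    g$length <- c(chr1 = len)
    ps <- manual_peaks("chr1", 10L, 20L, g$length)
    prof <- distance_profile(ps, g, n_bins = 7L)
    d_all <- pmin(0:(len - 1), len - 1 - (0:(len - 1)))
    oracle <- tabulate(
      findInterval(d_all, prof$bin_edges, rightmost.closed = TRUE),
      nbins = 7L
    )
    expect_equal(prof$available_bp, as.numeric(oracle))
    expect_equal(sum(prof$available_bp), len)
  }
})

test_that("a planted exponential gradient is recovered from the profile", {
  g <- build_genome(seed = 73L)
  decay <- 1e-5
  n <- 5000L
  pos <- withr::with_seed(77L, {
    b <- 5e5
    d <- -log(1 - runif(n) * (1 - exp(-decay * b))) / decay
    side <- runif(n) < 0.5
    chrom <- sample(g$chrom, n, replace = TRUE)
    start <- ifelse(side, round(d), 1e6 - 1 - round(d))
    data.frame(chrom = chrom, start = pmin(pmax(start, 0), 1e6 - 2))
  })
  ps <- manual_peaks(pos$chrom, as.integer(pos$start), as.integer(pos$start) + 1L, g$length)
  prof <- distance_profile(ps, g, n_bins = 20L)
  mids <- (prof$bin_edges[-1] + prof$bin_edges[-21]) / 2
  keep <- prof$n_peaks_per_bin > 0
  fit <- stats::lm(log(prof$density[keep]) ~ mids[keep])
  expect_lt(abs(-stats::coef(fit)[[2]] - decay) / decay, 0.2)
})

test_that("profiles conserve counts and are invariant to relabeling and reflection", {
  g <- small_genome()
  sites <- plant_sites(g, small_condition(n_int = 30L), seed = 83L)
  m <- sites$start + (sites$end - sites$start) %/% 2L
  ps <- manual_peaks(sites$chrom, m, m + 1L, g$length)
  prof <- distance_profile(ps, g, n_bins = 10L)
  expect_equal(sum(prof$n_peaks_per_bin), nrow(sites))

  # reflect chr1 coordinates
  i <- sites$chrom == "chr1"
  m_refl <- ifelse(i, g$length[["chr1"]] - 1L - m, m)
  prof_r <- distance_profile(
    manual_peaks(sites$chrom, m_refl, m_refl + 1L, g$length), g, n_bins = 10L
  )
  expect_equal(prof_r$n_peaks_per_bin, prof$n_peaks_per_bin)

  # swap chromosome labels
  swap <- ifelse(sites$chrom == "chr1", "chr2", "chr1")
  prof_s <- distance_profile(
    manual_peaks(swap, m, m + 1L, g$length), g, n_bins = 10L
  )
  expect_equal(prof_s$n_peaks_per_bin, prof$n_peaks_per_bin)
})

test_that("telomeric peaks are excluded and stray midpoints rejected", {
  g <- small_genome()
  ps <- manual_peaks(
    rep("chr1", 2), c(100L, 30000L), c(200L, 30100L), g$length,
    label = c("telomeric", "interstitial")
  )
  prof <- distance_profile(ps, g)
  expect_equal(sum(prof$n_peaks_per_bin), 1L)
  bad <- manual_peaks("chr1", 70000L, 70100L, g$length)
  expect_error(distance_profile(bad, g), "outside the genome")
})

test_that("gradient statistics behave on canonical profiles", {
  mk_prof <- function(density) {
    structure(
      list(
        bin_edges = seq(0, length(density)), n_peaks_per_bin = rep(1L, length(density)),
        available_bp = rep(1e6, length(density)), density = density,
        n_bins = length(density), origin = "chrom_end", n_peaks = length(density)
      ),
      class = "density_profile"
    )
  }
  dec <- gradient_stats(mk_prof(c(10, 8, 6, 4, 2)))
  expect_equal(dec$trend_corr, -1)
  flat <- gradient_stats(mk_prof(rep(3, 6)))
  expect_equal(flat$evenness_cv, 0)
  expect_equal(flat$subtel_ratio, 1)
  expect_error(gradient_stats(mk_prof(rep(0, 5))), "all-zero")
  two <- mk_prof(c(1, 2))
  expect_error(gradient_stats(two), "3 strata")
})

test_that("distance can be measured from the telomere tract boundary", {
  g <- small_genome() # tract 600 bp
  ps <- manual_peaks("chr1", 700L, 800L, g$length)
  p_end <- distance_profile(ps, g, n_bins = 10L, origin = "chrom_end")
  p_tr <- distance_profile(ps, g, n_bins = 10L, origin = "tract_boundary")
  # midpoint 750: distance 750 from the end, 150 from the tract boundary
  expect_equal(sum(p_end$n_peaks_per_bin), 1L)
  expect_equal(sum(p_tr$n_peaks_per_bin), 1L)
  expect_equal(sum(p_tr$available_bp), 2 * (60000 - 2 * 600)) # both chromosomes
})
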