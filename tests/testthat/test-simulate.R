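test_that("simulation conserves depth and read length exactly", {
  g <- small_genome()
  sites <- plant_sites(g, small_condition(), seed = 2L)
  rs <- simulate_sample(g, sites, small_condition(), "chip", depth = 5000, seed = 3L)
  expect_equal(length(rs$sequences), 5000L)
  expect_true(all(nchar(rs$sequences) == 50L))
  expect_equal(nrow(rs$truth), 5000L)
})

test_that("identical inputs give byte-identical FASTQ output", {
  g <- small_genome()
  sites <- plant_sites(g, small_condition(), seed = 2L)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(simulate_sample(g, sites, small_condition(), "chip", 2000, seed = 5L), f1)
  write_fastq(simulate_sample(g, sites, small_condition(), "chip", 2000, seed = 5L), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  rs3 <- simulate_sample(g, sites, small_condition(), "chip", 2000, seed = 6L)
  expect_false(identical(read_fastq(f1), stats::setNames(rs3$sequences, rs3$ids)))
})

test_that("input read starts hit telomeric tracts at the genomic rate", {
  g <- small_genome()
  sites <- plant_sites(g, small_condition(), seed = 2L)
  rs <- simulate_sample(g, sites, small_condition(), "input", depth = 10000, seed = 7L)
  tr <- g$tracts
  in_tract <- vapply(seq_len(nrow(rs$truth)), function(i) {
    any(tr$chrom == rs$truth$chrom[i] &
      tr$start <= rs$truth$start[i] & rs$truth$start[i] < tr$end)
  }, logical(1))
  p_exp <- sum(tr$end - tr$start) / sum(g$length) # binomial oracle
  sd3 <- 3 * sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(mean(in_tract) - p_exp), sd3)
})

test_that("knockout ChIP is indistinguishable from input in telomeric content", {
  g <- small_genome()
  sites <- plant_sites(g, small_condition(), seed = 2L)
  ko <- small_condition(rap1 = "KO")
  ok <- vapply(1:20, function(s) {
    a <- count_telomeric_reads(simulate_sample(g, sites, ko, "chip", 20000, seed = 100 + s))
    b <- count_telomeric_reads(simulate_sample(g, sites, ko, "input", 20000, seed = 200 + s))
    p <- suppressWarnings(stats::prop.test(
      c(a$telomeric_reads, b$telomeric_reads),
      c(a$total_reads, b$total_reads)
    )$p.value)
    p > 0.01
  }, logical(1))
  expect_gte(sum(ok), 19L)
})

test_that("telomeric read allocation scales with telomere_scale", {
  g <- small_genome()
  sites <- plant_sites(g, small_condition(), seed = 2L)
  frac_at <- function(scale, seed) {
    cond <- condition_spec(
      generation = if (scale == 1) "G0" else "G3", telomere_scale = scale,
      n_subtelomeric_sites = 5L, n_interstitial_sites = 10L
    )
    rs <- simulate_sample(g, sites, cond, "chip", depth = 50000, seed = seed)
    mean(rs$truth$category == "telomere")
  }
  ratio <- frac_at(0.3, 11L) / frac_at(1, 12L)
  expect_lt(abs(ratio - 0.3) / 0.3, 0.15)
})

test_that("counted telomeric reads are linear in telomere_scale", {
  g <- build_genome(seed = 31L) # full-size default genome
  sites <- plant_sites(g, condition_spec(), seed = 32L)
  scales <- c(1, 0.6, 0.3)
  counts <- vapply(seq_along(scales), function(i) {
    cond <- condition_spec(
      generation = c("G0", "G1", "G3")[i], telomere_scale = scales[i]
    )
    rs <- simulate_sample(g, sites, cond, "chip", depth = 1e5, seed = 300 + i)
    count_telomeric_reads(rs)$telomeric_reads
  }, numeric(1))
  r2 <- summary(stats::lm(counts ~ scales))$r.squared
  expect_gt(r2, 0.95)
})

test_that("substitution errors perturb reads but stay deterministic", {
  g <- small_genome()
  sites <- plant_sites(g, small_condition(), seed = 2L)
  clean <- simulate_sample(g, sites, small_condition(), "input", 500, seed = 9L)
  noisy1 <- simulate_sample(g, sites, small_condition(), "input", 500,
    seed = 9L, error_rate = 0.02
  )
  noisy2 <- simulate_sample(g, sites, small_condition(), "input", 500,
    seed = 9L, error_rate = 0.02
  )
  expect_identical(noisy1$sequences, noisy2$sequences)
  expect_false(identical(clean$sequences, noisy1$sequences))
  expect_identical(clean$truth$start, noisy1$truth$start)
})

test_that("a depth too low for telomeric coverage warns rather than errors", {
  g <- small_genome()
  sites <- plant_sites(g, small_condition(), seed = 2L)
  expect_warning(
    simulate_sample(g, sites, small_condition(), "input", depth = 10, seed = 1L),
    "expected telomeric reads"
  )
})
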