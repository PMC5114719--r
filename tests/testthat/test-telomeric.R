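test_that("the repeat-run definition is applied exactly", {
  r_tel <- paste0(strrep("TTAGGG", 8), "TT")
  r_rc <- paste0(strrep("CCCTAA", 8), "GG")
  r_n <- paste0(strrep("TTAGGG", 4), "N", substr(strrep("TTAGGG", 8), 1, 25))
  expect_equal(count_telomeric_reads(r_tel)$telomeric_reads, 1L)
  expect_equal(count_telomeric_reads(r_rc, both_strands = TRUE)$telomeric_reads, 1L)
  expect_equal(count_telomeric_reads(r_rc, both_strands = FALSE)$telomeric_reads, 0L)
  expect_equal(count_telomeric_reads(r_n)$telomeric_reads, 0L)
  # seven copies are not enough; a read with two distinct runs counts once
  expect_equal(count_telomeric_reads(paste0(strrep("TTAGGG", 7), "ACGTACGT"))$telomeric_reads, 0L)
  expect_equal(count_telomeric_reads(strrep("TTAGGG", 9))$telomeric_reads, 1L)
})

test_that("degenerate units and impossible run lengths are rejected", {
  expect_error(count_telomeric_reads("ACGT", unit = ""), "non-empty")
  expect_error(count_telomeric_reads("ACGT", unit = "TTAGGN"), "A/C/G/T")
  expect_error(
    count_telomeric_reads(strrep("A", 50), unit = "TTAGGG", min_copies = 9L),
    "undefined"
  )
})

test_that("the scan agrees with an independent Biostrings pattern count", {
  g <- small_genome()
  sites <- plant_sites(g, small_condition(), seed = 2L)
  rs <- simulate_sample(g, sites, small_condition(), "input", 10000, seed = 13L)
  mine <- count_telomeric_reads(rs)$telomeric_reads
  dss <- Biostrings::DNAStringSet(rs$sequences)
  pat <- strrep("TTAGGG", 8)
  oracle <- sum(
    Biostrings::vcountPattern(pat, dss) > 0 |
      Biostrings::vcountPattern(pat, Biostrings::reverseComplement(dss)) > 0
  )
  expect_gt(mine, 0)
  expect_equal(mine, oracle)
})

test_that("counting respects strand symmetry and run-length monotonicity", {
  g <- small_genome()
  sites <- plant_sites(g, small_condition(), seed = 2L)
  rs <- simulate_sample(g, sites, small_condition(), "chip", 5000, seed = 17L)
  fwd <- count_telomeric_reads(rs$sequences)$telomeric_reads
  rev <- count_telomeric_reads(rap1shift:::revcomp_chr(rs$sequences))$telomeric_reads
  expect_equal(fwd, rev)
  counts <- vapply(1:8, function(k) {
    count_telomeric_reads(rs$sequences, min_copies = k)$telomeric_reads
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a random half subsample reproduces the telomeric fraction", {
  g <- small_genome()
  sites <- plant_sites(g, small_condition(), seed = 2L)
  rs <- simulate_sample(g, sites, small_condition(), "chip", 20000, seed = 19L)
  full <- count_telomeric_reads(rs)
  idx <- withr::with_seed(23L, sample.int(20000, 10000))
  half <- count_telomeric_reads(rs$sequences[idx])
  sd3 <- 3 * sqrt(full$fraction * (1 - full$fraction) / 10000)
  expect_lt(abs(half$fraction - full$fraction), sd3)
})

test_that("FASTQ input (plain and gzip) gives the same counts as in-memory reads", {
  g <- small_genome()
  sites <- plant_sites(g, small_condition(), seed = 2L)
  rs <- simulate_sample(g, sites, small_condition(), "input", 2000, seed = 29L)
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rs, f)
  fgz <- withr::local_tempfile(fileext = ".fastq.gz")
  con <- gzfile(fgz, "w")
  writeLines(readLines(f), con)
  close(con)
  mem <- count_telomeric_reads(rs)
  expect_equal(count_telomeric_reads(f)$telomeric_reads, mem$telomeric_reads)
  expect_equal(count_telomeric_reads(fgz)$telomeric_reads, mem$telomeric_reads)
})

test_that("enrichment identities and error paths hold", {
  a <- count_telomeric_reads(c(strrep("TTAGGG", 9), strrep("ACGTAC", 9)))
  expect_equal(telomeric_enrichment(a, a)$fold_vs_input, 1)
  ref <- telomeric_enrichment(a, a)
  e <- telomeric_enrichment(a, a, reference = ref)
  expect_equal(e$fold_vs_reference, 1)
  expect_equal(ref$fold_vs_reference, 1) # the reference sample itself
  none <- count_telomeric_reads(strrep("ACGTAC", 9))
  expect_error(telomeric_enrichment(a, none), "deeper input")
})

test_that("the sample report table normalizes to the reference row", {
  counts <- list(
    c1 = count_telomeric_reads(c(strrep("TTAGGG", 9), strrep("ACGTAC", 9))),
    c2 = count_telomeric_reads(c(strrep("TTAGGG", 9), rep(strrep("ACGTAC", 9), 3))),
    inp = count_telomeric_reads(c(strrep("TTAGGG", 9), rep(strrep("ACGTAC", 9), 7)))
  )
  pairs <- data.frame(sample = c("c1", "c2"), input = c("inp", "inp"))
  tab <- telomeric_report(counts, pairs, reference = "c1")
  expect_equal(tab$fold_vs_reference[tab$sample_id == "c1"], 1)
  expect_equal(
    tab$fold_vs_reference[tab$sample_id == "c2"],
    (0.25 / 0.125) / (0.5 / 0.125)
  )
})
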