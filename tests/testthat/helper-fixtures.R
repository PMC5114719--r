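# Small shared fixtures, built in code. The "small" genome keeps unit tests
# fast; acceptance checks use the full default study conditions.

small_genome <- function(seed = 11L, n_chrom = 2L) {
  build_genome(
    n_chrom = n_chrom, chrom_length = 60000L, telomere_units = 100L,
    subtelomere_len = 5000L, seed = seed
  )
}

small_condition <- function(rap1 = "WT", generation = "G0", telomere_scale = 1,
                            n_sub = 5L, n_int = 10L, decay = 1e-4) {
  condition_spec(
    generation = generation, rap1 = rap1, telomere_scale = telomere_scale,
    n_subtelomeric_sites = n_sub, n_interstitial_sites = n_int,
    gradient_decay = decay
  )
}

# Coverage track built directly from per-chromosome count vectors, for
# exercising the peak caller on hand-constructed inputs.
manual_track <- function(counts, bin_size = 200L, library_size = NULL,
                         chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- stats::setNames(
      vapply(counts, length, numeric(1)) * bin_size, names(counts)
    )
  }
  structure(
    list(
      bin_size = as.integer(bin_size),
      counts = lapply(counts, as.integer),
      library_size = library_size %||% sum(unlist(counts)),
      chrom_lengths = chrom_lengths
    ),
    class = "coverage_track"
  )
}

# Peak set built directly from intervals (labelled nontelomeric), for
# profile and overlap tests.
manual_peaks <- function(chrom, start, end, chrom_lengths,
                         label = "interstitial", p = 1e-6) {
  df <- data.frame(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    max_enrichment = 10, p_value = p, label = label,
    stringsAsFactors = FALSE
  )
  df <- df[order(match(df$chrom, names(chrom_lengths)), df$start), , drop = FALSE]
  structure(
    list(
      peaks = df, bin_size = 200L, p_cutoff = 1e-3,
      chrom_lengths = chrom_lengths,
      n_nontelomeric = sum(df$label != "telomeric")
    ),
    class = "peak_set"
  )
}

`%||%` <- rap1shift:::`%||%`

# Independent upper-tail Poisson oracle: direct pmf summation.
pois_tail_oracle <- function(count, lambda) {
  hi <- max(count + 200L, ceiling(lambda + 40 * sqrt(lambda) + 200))
  sum(stats::dpois(seq(count, hi), lambda))
}
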