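#' Count reads containing a perfect telomeric repeat run
#'
#' Alignment-free statistic computed on raw reads: a read is telomeric iff the
#' repeat unit concatenated `min_copies` times occurs as an exact substring of
#' the read or (with `both_strands`) of its reverse complement. A read counts
#' once regardless of match multiplicity; reads containing `N` never match.
#' With the defaults this is the `(TTAGGG)8`-in-50-nt statistic.
#'
#' @param reads A `read_set`, a character vector of sequences, a
#'   `DNAStringSet`, or a FASTQ path (plain or gzip).
#' @param unit Repeat unit (non-empty, over A/C/G/T).
#' @param min_copies Minimum number of consecutive perfect copies.
#' @param both_strands Also accept matches on the reverse complement.
#' @return An object of class `telomeric_count` with fields `total_reads`,
#'   `telomeric_reads` and `fraction`.
#' @export
count_telomeric_reads <- function(reads, unit = "TTAGGG", min_copies = 8L,
                                  both_strands = TRUE) {
  x <- as_sequences(reads)
  if (!nzchar(unit) || grepl("[^ACGT]", unit)) {
    stop("`unit` must be a non-empty string over A/C/G/T", call. = FALSE)
  }
  pat_len <- nchar(unit) * min_copies
  if (length(x) > 0 && pat_len > max(nchar(x))) {
    stop(sprintf(
      "min_copies x unit length (%d nt) exceeds the read length: statistic undefined",
      pat_len
    ), call. = FALSE)
  }
  pat <- strrep(unit, min_copies)
  hit <- grepl(pat, x, fixed = TRUE)
  if (both_strands) hit <- hit | grepl(pat, revcomp_chr(x), fixed = TRUE)
  structure(
    list(
      total_reads = length(x), telomeric_reads = sum(hit),
      fraction = if (length(x) > 0) sum(hit) / length(x) else NA_real_,
      unit = unit, min_copies = as.integer(min_copies),
      both_strands = both_strands
    ),
    class = "telomeric_count"
  )
}

as_sequences <- function(reads) {
  if (inherits(reads, "read_set")) {
    reads$sequences
  } else if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    unname(read_fastq(reads))
  } else if (methods::is(reads, "DNAStringSet")) {
    as.character(reads)
  } else if (is.character(reads)) {
    reads
  } else {
    stop("unsupported read container", call. = FALSE)
  }
}

#' @export
print.telomeric_count <- function(x, ...) {
  cat(sprintf(
    "telomeric_count: %d / %d reads (%.4f%%) contain (%s)%d%s\n",
    x$telomeric_reads, x$total_reads, 100 * x$fraction,
    x$unit, x$min_copies,
    if (x$both_strands) " on either strand" else " on the read strand"
  ))
  invisible(x)
}

#' Input-normalized telomeric enrichment of a ChIP sample
#'
#' `fold_vs_input` divides the ChIP telomeric read fraction by the matched
#' input's; `fold_vs_reference` further normalizes to a designated reference
#' sample (the reference itself has `fold_vs_reference = 1`).
#'
#' @param chip,input `telomeric_count` objects for the ChIP sample and its
#'   matched input.
#' @param reference Optional `telomeric_enrichment` of the reference sample;
#'   `NULL` marks this sample as the reference.
#' @param sample_id Optional label carried into reports.
#' @return An object of class `telomeric_enrichment`.
#' @export
telomeric_enrichment <- function(chip, input, reference = NULL, sample_id = NULL) {
  stopifnot(inherits(chip, "telomeric_count"), inherits(input, "telomeric_count"))
  if (input$telomeric_reads <= 0) {
    stop("matched input has zero telomeric reads; simulate a deeper input sample",
      call. = FALSE
    )
  }
  fvi <- chip$fraction / input$fraction
  fvr <- if (is.null(reference)) 1 else fvi / reference$fold_vs_input
  structure(
    list(
      sample_id = sample_id %||% NA_character_,
      fold_vs_input = fvi, fold_vs_reference = fvr,
      chip = chip, input = input
    ),
    class = "telomeric_enrichment"
  )
}

#' @export
print.telomeric_enrichment <- function(x, ...) {
  cat(sprintf(
    "telomeric_enrichment%s: fold_vs_input=%.3f fold_vs_reference=%.3f\n",
    if (is.na(x$sample_id)) "" else paste0(" [", x$sample_id, "]"),
    x$fold_vs_input, x$fold_vs_reference
  ))
  invisible(x)
}

#' Tabulate telomeric content and enrichment across samples
#'
#' @param counts Named list of `telomeric_count` objects.
#' @param pairs Data frame with columns `sample` (ChIP count name) and `input`
#'   (matched input count name).
#' @param reference Name (in `pairs$sample`) of the reference ChIP sample.
#' @return Data frame: sample_id, total, telomeric, fraction, fold_vs_input,
#'   fold_vs_reference.
#' @export
telomeric_report <- function(counts, pairs, reference = pairs$sample[1]) {
  ref_row <- match(reference, pairs$sample)
  if (is.na(ref_row)) stop("reference sample not found in `pairs`", call. = FALSE)
  ref <- telomeric_enrichment(counts[[pairs$sample[ref_row]]],
    counts[[pairs$input[ref_row]]],
    sample_id = reference
  )
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    id <- pairs$sample[i]
    e <- telomeric_enrichment(counts[[id]], counts[[pairs$input[i]]],
      reference = if (id == reference) NULL else ref, sample_id = id
    )
    data.frame(
      sample_id = id,
      total = counts[[id]]$total_reads,
      telomeric = counts[[id]]$telomeric_reads,
      fraction = counts[[id]]$fraction,
      fold_vs_input = e$fold_vs_input,
      fold_vs_reference = e$fold_vs_reference,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
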