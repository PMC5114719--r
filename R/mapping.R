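#' Map fixed-length reads to a toy genome by exact unique matching
#'
#' Deterministic stand-in for a read aligner, suitable for error-free
#' simulated reads: a read maps iff its sequence (or, on the reverse strand,
#' its reverse complement) occurs exactly once in the genome, with zero
#' mismatches. Reads with more than one occurrence are classified multimapped
#' and discarded -- in particular reads drawn from inside telomeric tracts,
#' which is why telomeric content must be quantified on raw reads before
#' alignment. Reads containing `N` (or any non-ACGT letter) are unmapped.
#'
#' @param reads A `read_set`, character vector, or `DNAStringSet`; all reads
#'   must have the same length.
#' @param genome A `genome_model`.
#' @return An `alignment_set`: `records` data frame (read_id, chrom, 0-based
#'   start, strand) for uniquely mapped reads plus `n_mapped`,
#'   `n_multimapped`, `n_unmapped` counts and chromosome lengths.
#' @export
map_reads <- function(reads, genome) {
  stopifnot(inherits(genome, "genome_model"))
  seqs <- as_sequences(reads)
  ids <- if (inherits(reads, "read_set")) reads$ids else names(seqs) %||% sprintf("r%06d", seq_along(seqs))
  if (is.null(ids)) ids <- sprintf("r%06d", seq_along(seqs))
  wd <- unique(nchar(seqs))
  if (length(wd) != 1L) {
    stop("all reads must have the same length for exact-hash mapping", call. = FALSE)
  }
  clean <- !grepl("[^ACGT]", seqs)
  n <- length(seqs)

  dss <- Biostrings::DNAStringSet(seqs[clean])
  subjects <- lapply(genome$seq, Biostrings::DNAString)

  cf <- cr <- integer(length(dss))
  if (length(dss) > 0) {
    pd_f <- Biostrings::PDict(dss)
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(dss))
    for (s in subjects) {
      cf <- cf + Biostrings::countPDict(pd_f, s)
      cr <- cr + Biostrings::countPDict(pd_r, s)
    }
  }
  tot <- cf + cr
  uniq <- tot == 1L

  records <- data.frame(
    read_id = character(0), chrom = character(0),
    start = integer(0), strand = character(0), stringsAsFactors = FALSE
  )
  if (any(uniq)) {
    u_ids <- ids[clean][uniq]
    dss_u <- dss[uniq]
    pdu_f <- Biostrings::PDict(dss_u)
    pdu_r <- Biostrings::PDict(Biostrings::reverseComplement(dss_u))
    parts <- list()
    for (cn in genome$chrom) {
      for (str in c("+", "-")) {
        m <- Biostrings::matchPDict(
          if (str == "+") pdu_f else pdu_r, subjects[[cn]]
        )
        nh <- IRanges::elementNROWS(m)
        hit <- which(nh > 0L)
        if (length(hit) > 0) {
          starts <- vapply(
            Biostrings::startIndex(m)[hit], function(v) v[1],
            integer(1)
          )
          parts[[length(parts) + 1L]] <- data.frame(
            read_id = u_ids[hit], chrom = cn,
            start = starts - 1L, strand = str, stringsAsFactors = FALSE
          )
        }
      }
    }
    records <- do.call(rbind, parts)
    records <- records[match(u_ids, records$read_id), , drop = FALSE]
    rownames(records) <- NULL
  }

  structure(
    list(
      records = records,
      n_mapped = sum(uniq),
      n_multimapped = sum(tot > 1L),
      n_unmapped = sum(tot == 0L) + sum(!clean),
      total = n, read_length = wd,
      chrom_lengths = genome$length
    ),
    class = "alignment_set"
  )
}

#' Alignments taken directly from a read set's recorded sampling positions
#'
#' Bypasses sequence matching entirely: every read is "mapped" to the position
#' it was drawn from. Useful as the construction oracle in tests and for
#' large repeated simulations where the mapping step is not under study.
#'
#' @param reads A `read_set`.
#' @param genome A `genome_model` (for chromosome lengths).
#' @return An `alignment_set` with one record per read.
#' @export
alignments_from_truth <- function(reads, genome) {
  stopifnot(inherits(reads, "read_set"), inherits(genome, "genome_model"))
  structure(
    list(
      records = data.frame(
        read_id = reads$ids, chrom = reads$truth$chrom,
        start = reads$truth$start, strand = reads$truth$strand,
        stringsAsFactors = FALSE
      ),
      n_mapped = reads$depth, n_multimapped = 0L, n_unmapped = 0L,
      total = reads$depth, read_length = reads$read_length,
      chrom_lengths = genome$length
    ),
    class = "alignment_set"
  )
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf(
    "alignment_set: %d reads | %d mapped, %d multimapped (discarded), %d unmapped\n",
    x$total, x$n_mapped, x$n_multimapped, x$n_unmapped
  ))
  invisible(x)
}

#' Write uniquely mapped reads as BED6
#'
#' One record per mapped read, 0-based half-open, score 0.
#'
#' @param aln An `alignment_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments_bed <- function(aln, path) {
  r <- aln$records
  write_bed(data.frame(r$chrom, r$start, r$start + aln$read_length,
    r$read_id, 0L, r$strand,
    stringsAsFactors = FALSE
  ), path)
}

#' Load precomputed alignments from BED6, bypassing the mapper
#'
#' @param path BED6 path (chrom, start, end, read_id, score, strand).
#' @param genome A `genome_model` supplying chromosome lengths.
#' @return An `alignment_set` (multimapped/unmapped counts are zero: the file
#'   is taken to contain uniquely mapped reads only).
#' @export
read_alignments_bed <- function(path, genome) {
  df <- read_bed(path, c("chrom", "start", "end", "read_id", "score", "strand"))
  bad <- setdiff(unique(df$chrom), genome$chrom)
  if (length(bad) > 0) {
    stop("alignments on chromosomes absent from the genome: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      records = df[, c("read_id", "chrom", "start", "strand")],
      n_mapped = nrow(df), n_multimapped = 0L, n_unmapped = 0L,
      total = nrow(df), read_length = df$end[1] - df$start[1],
      chrom_lengths = genome$length
    ),
    class = "alignment_set"
  )
}
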