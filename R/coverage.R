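#' Bin read starts into a fixed-width coverage track
#'
#' Counts read starts per half-open bin `[k*b, (k+1)*b)` on every chromosome.
#' The sum over all bins equals the number of mapped reads.
#'
#' @param aln An `alignment_set`.
#' @param bin_size Bin width in bp (default 200, roughly Illumina fragment
#'   scale).
#' @return A `coverage_track`: per-chromosome integer count vectors of length
#'   `ceiling(chrom_length / bin_size)`, the bin size, and the library size
#'   (mapped read count).
#' @export
bin_coverage <- function(aln, bin_size = 200L) {
  stopifnot(inherits(aln, "alignment_set"))
  bin_size <- as.integer(bin_size)
  if (bin_size < 1L) stop("`bin_size` must be >= 1", call. = FALSE)
  counts <- lapply(names(aln$chrom_lengths), function(cn) {
    nb <- as.integer(ceiling(aln$chrom_lengths[[cn]] / bin_size))
    st <- aln$records$start[aln$records$chrom == cn]
    if (length(st) == 0L) integer(nb) else tabulate(st %/% bin_size + 1L, nbins = nb)
  })
  names(counts) <- names(aln$chrom_lengths)
  structure(
    list(
      bin_size = bin_size, counts = counts,
      library_size = aln$n_mapped,
      chrom_lengths = aln$chrom_lengths
    ),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "coverage_track: %d chromosome(s), bin_size=%d, library_size=%d\n",
    length(x$counts), x$bin_size, x$library_size
  ))
  invisible(x)
}

#' Write a coverage track as BEDGraph
#'
#' Zero-count bins are written too, so tracks round-trip exactly.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$counts), function(cn) {
    v <- track$counts[[cn]]
    st <- (seq_along(v) - 1L) * track$bin_size
    data.frame(
      chrom = cn, start = st,
      end = pmin(st + track$bin_size, track$chrom_lengths[[cn]]),
      count = v, stringsAsFactors = FALSE
    )
  })
  write_bed(do.call(rbind, rows), path)
}

#' Read a BEDGraph written by [write_bedgraph()] back into a coverage track
#'
#' @param path BEDGraph path.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path) {
  df <- read_bed(path, c("chrom", "start", "end", "count"))
  bin_size <- max(df$end - df$start)
  chroms <- unique(df$chrom)
  counts <- lapply(chroms, function(cn) as.integer(df$count[df$chrom == cn]))
  names(counts) <- chroms
  lens <- vapply(chroms, function(cn) max(df$end[df$chrom == cn]), numeric(1))
  structure(
    list(
      bin_size = as.integer(bin_size), counts = counts,
      library_size = sum(df$count), chrom_lengths = lens
    ),
    class = "coverage_track"
  )
}
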