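#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the Mersenne-Twister generator seeded at `seed`, restoring
#' the caller's RNG state afterwards so simulations never perturb each other.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

#' Derive a reproducible sub-seed from a base seed
#'
#' Spreads a base seed and a small offset over the 32-bit range so that every
#' sample in a run gets its own deterministic RNG stream.
#'
#' @param seed Base integer seed.
#' @param offset Non-negative integer stream index.
#' @return An integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset) * 9973 + 1) %% 2147483647)
}

#' Reverse-complement a character vector of DNA sequences
#'
#' @param x Character vector over the alphabet A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp_chr <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write intervals as a BED file
#'
#' Coordinates are 0-based half-open throughout the package, i.e. already in
#' BED convention; columns beyond the first three are written as given.
#'
#' @param df Data frame whose first three columns are chrom, start, end.
#' @param path Output path.
#' @return `path`, invisibly.
#' @keywords internal
write_bed <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a BED file into a data frame
#'
#' @param path BED path (0-based half-open intervals).
#' @param col_names Optional names for the columns present in the file.
#' @return Data frame with at least chrom/start/end.
#' @keywords internal
read_bed <- function(path, col_names = NULL) {
  df <- utils::read.table(path,
    sep = "\t", header = FALSE,
    stringsAsFactors = FALSE
  )
  base <- c("chrom", "start", "end")
  if (is.null(col_names)) {
    col_names <- c(base, paste0("V", seq_len(max(0L, ncol(df) - 3L)) + 3L))
  }
  names(df) <- col_names[seq_len(ncol(df))]
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
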