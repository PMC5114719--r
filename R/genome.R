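TELOMERE_UNIT <- "TTAGGG"

#' Build a toy linear genome with terminal telomeric tracts
#'
#' Constructs a small multi-chromosome genome in which each chromosome starts
#' with a perfect `(TTAGGG)n` tract on the forward strand and ends with the
#' forward-strand representation of the opposite G-strand, `(CCCTAA)n`. The
#' intervening "arm" sequence is random and is rejected/resampled until it
#' contains no run of eight repeat units on either strand, so that every
#' telomere-like 48-mer in the genome lies inside a recorded tract.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of every chromosome in bp.
#' @param telomere_units Perfect `TTAGGG` repeat units per chromosome end
#'   before scaling.
#' @param subtelomere_len Width in bp of the subtelomeric window measured
#'   inward from each telomeric tract boundary.
#' @param telomere_scale Fraction in (0, 1] multiplying `telomere_units`,
#'   emulating tract shortening across telomerase-null generations.
#' @param seed Integer seed; identical arguments and seed give byte-identical
#'   sequence.
#' @return An object of class `genome_model`: chromosome names and lengths,
#'   sequences, the scaled per-end repeat-unit count, and 0-based half-open
#'   `tracts` and `subtelomeres` interval tables.
#' @export
build_genome <- function(n_chrom = 3L, chrom_length = 1e6, telomere_units = 800L,
                         subtelomere_len = 25000L, telomere_scale = 1,
                         seed = 1L) {
  if (n_chrom < 1L) stop("need at least one chromosome", call. = FALSE)
  if (!(telomere_scale > 0 && telomere_scale <= 1)) {
    stop("`telomere_scale` must lie in (0, 1]", call. = FALSE)
  }
  units <- as.integer(round(telomere_units * telomere_scale))
  if (units < 1L) stop("scaled telomere tract has fewer than one repeat unit", call. = FALSE)
  tract_bp <- 6L * units
  chrom_length <- as.integer(chrom_length)
  if (tract_bp > 0.1 * chrom_length) {
    stop(sprintf(
      "telomere tract (%d bp) exceeds 10%% of chromosome length (%d bp)",
      tract_bp, chrom_length
    ), call. = FALSE)
  }
  if (chrom_length < 2L * (tract_bp + subtelomere_len)) {
    stop("chromosome too short for two telomere tracts plus subtelomeres", call. = FALSE)
  }

  chrom <- paste0("chr", seq_len(n_chrom))
  left_tract <- strrep(TELOMERE_UNIT, units)
  right_tract <- strrep("CCCTAA", units)
  arm_len <- chrom_length - 2L * tract_bp

  seqs <- with_seed(seed, {
    vapply(chrom, function(cn) {
      arm <- paste(sample(c("A", "C", "G", "T"), arm_len, replace = TRUE),
        collapse = ""
      )
      s <- paste0(left_tract, arm, right_tract)
      resample_repeat_windows(s, tract_bp, chrom_length)
    }, character(1))
  })

  lens <- stats::setNames(rep(chrom_length, n_chrom), chrom)
  tracts <- data.frame(
    chrom = rep(chrom, each = 2L),
    start = rep(c(0L, chrom_length - tract_bp), n_chrom),
    end = rep(c(tract_bp, chrom_length), n_chrom),
    side = rep(c("left", "right"), n_chrom),
    stringsAsFactors = FALSE
  )
  subtel <- data.frame(
    chrom = rep(chrom, each = 2L),
    start = rep(c(tract_bp, chrom_length - tract_bp - subtelomere_len), n_chrom),
    end = rep(c(tract_bp + subtelomere_len, chrom_length - tract_bp), n_chrom),
    side = rep(c("left", "right"), n_chrom),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      chrom = chrom, length = lens, seq = seqs,
      telomere_units = units, tract_bp = tract_bp,
      subtelomere_len = as.integer(subtelomere_len),
      tracts = tracts, subtelomeres = subtel, seed = as.integer(seed)
    ),
    class = "genome_model"
  )
}

# Resample 60-bp arm windows until no 8-unit telomeric run survives outside
# the two terminal tracts. The chance of a random hit is ~4^-48 per window;
# the loop exists for correctness, not because it is expected to fire.
resample_repeat_windows <- function(s, tract_bp, chrom_length, max_iter = 100L) {
  pats <- c(strrep(TELOMERE_UNIT, 8L), strrep("CCCTAA", 8L))
  for (i in seq_len(max_iter)) {
    bad <- integer(0)
    for (p in pats) {
      m <- gregexpr(p, s, fixed = TRUE)[[1]]
      if (m[1] != -1L) {
        st <- as.integer(m) # 1-based match starts
        en <- st + nchar(p) - 1L
        outside <- !(en <= tract_bp | st > chrom_length - tract_bp)
        bad <- c(bad, st[outside])
      }
    }
    if (length(bad) == 0L) return(s)
    for (b in bad) {
      w0 <- max(tract_bp + 1L, b - 6L)
      w1 <- min(chrom_length - tract_bp, b + 53L)
      repl <- paste(sample(c("A", "C", "G", "T"), w1 - w0 + 1L, replace = TRUE),
        collapse = ""
      )
      substr(s, w0, w1) <- repl
    }
  }
  stop("could not purge telomere-like repeats from arm sequence", call. = FALSE)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "genome_model: %d chromosome(s) x %s bp; %d TTAGGG units/end (%d bp tract), %d bp subtelomere\n",
    length(x$chrom), format(x$length[[1]], big.mark = ","),
    x$telomere_units, x$tract_bp, x$subtelomere_len
  ))
  invisible(x)
}

#' Persist a genome model as FASTA plus ground-truth BED files
#'
#' Writes `genome.fa`, `telomere_tracts.bed` and `subtelomeres.bed` (0-based
#' half-open, column 4 = end side) into `dir`.
#'
#' @param genome A `genome_model`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "genome_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa")
  dss <- Biostrings::DNAStringSet(genome$seq)
  names(dss) <- genome$chrom
  Biostrings::writeXStringSet(dss, fa, width = 70L)
  tr <- file.path(dir, "telomere_tracts.bed")
  sb <- file.path(dir, "subtelomeres.bed")
  write_bed(genome$tracts, tr)
  write_bed(genome$subtelomeres, sb)
  invisible(c(fasta = fa, tracts = tr, subtelomeres = sb))
}

#' Load a genome model from FASTA and ground-truth BED files
#'
#' Counterpart of [write_genome()] for running the analysis on externally
#' provided toy genomes.
#'
#' @param fasta Path to the genome FASTA.
#' @param tracts_bed Path to the telomere-tract BED (chrom, start, end, side).
#' @param subtelomeres_bed Path to the subtelomere BED (same columns).
#' @return A `genome_model`.
#' @export
load_genome <- function(fasta, tracts_bed, subtelomeres_bed) {
  dss <- Biostrings::readDNAStringSet(fasta)
  seqs <- stats::setNames(as.character(dss), names(dss))
  tracts <- read_bed(tracts_bed, c("chrom", "start", "end", "side"))
  subtel <- read_bed(subtelomeres_bed, c("chrom", "start", "end", "side"))
  units <- as.integer((tracts$end[1] - tracts$start[1]) / 6L)
  structure(
    list(
      chrom = names(seqs), length = vapply(seqs, nchar, numeric(1)),
      seq = seqs, telomere_units = units, tract_bp = 6L * units,
      subtelomere_len = as.integer(subtel$end[1] - subtel$start[1]),
      tracts = tracts, subtelomeres = subtel, seed = NA_integer_
    ),
    class = "genome_model"
  )
}
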