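#' Simulate a ChIP or input read sample with known ground truth
#'
#' Draws fixed-length single-end reads from a toy genome under the point
#' sampling model (read starts, no fragment-length convolution). Input samples
#' and knockout (RAP1-KO) ChIP samples draw uniformly from the genome, so KO
#' ChIP is distributionally identical to input. Wild-type ChIP allocates a
#' fraction `tel_frac * telomere_scale` of reads to positions fully inside the
#' telomeric tracts (telomere-bound protein proportional to tract length), a
#' fraction `site_frac` to planted sites in proportion to their occupancy
#' weights, and the remainder to uniform background. Each read is taken from
#' the forward or reverse strand with probability 1/2.
#'
#' @param genome A `genome_model`.
#' @param sites A `site_catalog` (may be empty; ignored for input/KO).
#' @param condition A `condition_spec`.
#' @param role `"chip"` or `"input"`.
#' @param depth Number of reads to emit (exactly).
#' @param seed Integer seed; identical arguments give byte-identical reads.
#' @param error_rate Per-base substitution error rate (default 0).
#' @param read_length Read length in nt (default 50).
#' @return An object of class `read_set`: character vector `sequences`, read
#'   `ids`, the sampling `truth` table (chrom, 0-based start, strand,
#'   category), and the sample metadata.
#' @export
simulate_sample <- function(genome, sites, condition, role = c("chip", "input"),
                            depth = 1e5, seed = 1L, error_rate = 0,
                            read_length = 50L) {
  stopifnot(inherits(genome, "genome_model"), inherits(condition, "condition_spec"))
  role <- match.arg(role)
  depth <- as.integer(depth)
  rl <- as.integer(read_length)
  if (depth < 1L) stop("`depth` must be >= 1", call. = FALSE)
  if (any(genome$length < rl)) stop("chromosome shorter than read length", call. = FALSE)

  specific <- role == "chip" && condition$rap1 == "WT"
  p_tel <- if (specific) condition$tel_frac * condition$telomere_scale else 0
  p_site <- if (specific && !is.null(sites) && nrow(sites) > 0) condition$site_frac else 0
  p_bg <- 1 - p_tel - p_site
  if (p_bg < 0) stop("read allocation fractions exceed 1", call. = FALSE)

  exp_tel <- depth * if (specific) p_tel else sum(genome$tracts$end - genome$tracts$start) / sum(genome$length)
  if (exp_tel < 1) {
    warning(sprintf("expected telomeric reads < 1 (%.3g) at depth %d", exp_tel, depth),
      call. = FALSE
    )
  }

  with_seed(seed, {
    category <- sample(c("telomere", "site", "background"), depth,
      replace = TRUE, prob = c(p_tel, p_site, p_bg)
    )

    chrom <- character(depth)
    start <- integer(depth)

    i_tel <- which(category == "telomere")
    if (length(i_tel) > 0) {
      tr <- genome$tracts
      elig <- pmax(0L, tr$end - tr$start - rl + 1L) # fully-inside starts
      if (sum(elig) == 0L) stop("telomeric tracts shorter than the read length", call. = FALSE)
      ti <- sample.int(nrow(tr), length(i_tel), replace = TRUE, prob = elig)
      off <- floor(stats::runif(length(i_tel)) * elig[ti])
      chrom[i_tel] <- tr$chrom[ti]
      start[i_tel] <- tr$start[ti] + as.integer(off)
    }

    i_site <- which(category == "site")
    if (length(i_site) > 0) {
      si <- sample.int(nrow(sites), length(i_site), replace = TRUE, prob = sites$occupancy)
      n_start <- pmax(1L, sites$end - sites$start - rl + 1L)
      off <- floor(stats::runif(length(i_site)) * n_start[si])
      chrom[i_site] <- sites$chrom[si]
      start[i_site] <- sites$start[si] + as.integer(off)
    }

    i_bg <- which(category == "background")
    if (length(i_bg) > 0) {
      valid <- genome$length - rl + 1L
      ci <- sample.int(length(genome$chrom), length(i_bg), replace = TRUE, prob = valid)
      off <- floor(stats::runif(length(i_bg)) * valid[ci])
      chrom[i_bg] <- genome$chrom[ci]
      start[i_bg] <- as.integer(off)
    }

    seqs <- character(depth)
    for (cn in genome$chrom) {
      idx <- which(chrom == cn)
      if (length(idx) > 0) {
        seqs[idx] <- substring(genome$seq[[cn]], start[idx] + 1L, start[idx] + rl)
      }
    }

    minus <- stats::runif(depth) < 0.5
    if (any(minus)) seqs[minus] <- revcomp_chr(seqs[minus])

    if (error_rate > 0) {
      n_err <- stats::rbinom(depth, rl, error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(rl, n_err[i])
        s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
        seqs[i] <- paste(s, collapse = "")
      }
    }

    ids <- sprintf(
      "%s_%s_%s_s%d_r%06d", role, condition$generation, condition$rap1,
      as.integer(seed), seq_len(depth)
    )
    structure(
      list(
        sequences = seqs, ids = ids, role = role, condition = condition,
        seed = as.integer(seed), depth = depth, read_length = rl,
        error_rate = error_rate,
        truth = data.frame(
          chrom = chrom, start = start,
          strand = ifelse(minus, "-", "+"),
          category = category, stringsAsFactors = FALSE
        )
      ),
      class = "read_set"
    )
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf(
    "read_set: %d x %d nt reads | role=%s | %s / RAP1-%s | seed=%d\n",
    x$depth, x$read_length, x$role,
    x$condition$generation, x$condition$rap1, x$seed
  ))
  invisible(x)
}

#' Write a read set as FASTQ
#'
#' Base qualities are constant `I` (Phred 40); quality is unused downstream.
#' Output is byte-identical for identical read sets.
#'
#' @param reads A `read_set`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  qual <- strrep("I", reads$read_length)
  lines <- character(4L * reads$depth)
  lines[seq(1, length(lines), 4)] <- paste0("@", reads$ids)
  lines[seq(2, length(lines), 4)] <- reads$sequences
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- qual
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTQ file (plain or gzip)
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(dss), sub(" .*", "", names(dss)))
}
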