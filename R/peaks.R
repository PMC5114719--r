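#' Call enrichment peaks from binned coverage with a Poisson per-bin test
#'
#' For every bin the control expectation is
#' `lambda = (control count + pseudocount) * chip library / control library`
#' and the per-bin p-value is the upper Poisson tail
#' `P(X >= chip count | lambda)`. Bins with `p < p_cutoff` and
#' `chip count > lambda` are significant; runs of significant bins separated
#' by at most `merge_gap_bins` non-significant bins merge into one peak. A
#' peak's p-value is the minimum over its member bins and its enrichment the
#' maximum member `count / lambda`. The intended control is the matched
#' knockout ChIP (the wild-type-vs-null comparison); an input track may be
#' supplied instead.
#'
#' @param chip,control `coverage_track`s on the same genome and binning.
#' @param p_cutoff Raw per-bin p-value cutoff (no multiplicity correction by
#'   default, matching a plain 1e-3 cutoff).
#' @param pseudocount Added to control counts before scaling, preventing
#'   zero-expectation singularities.
#' @param merge_gap_bins Maximum run of non-significant bins bridged when
#'   merging.
#' @param background_floor Floor the per-bin expectation at the genome-wide
#'   scaled control rate. The local scaled control alone is anti-conservative
#'   wherever the control count fluctuates low; flooring it at the global
#'   background rate keeps the test calibrated without touching genuinely
#'   enriched bins.
#' @param fdr Apply Benjamini-Hochberg across bins and test the adjusted
#'   p-values against `p_cutoff` instead (off by default).
#' @return A `peak_set`: data frame of peaks (chrom, start, end 0-based
#'   half-open, max_enrichment, p_value), sorted and non-overlapping.
#' @export
call_peaks <- function(chip, control, p_cutoff = 1e-3, pseudocount = 0.5,
                       merge_gap_bins = 1L, background_floor = TRUE,
                       fdr = FALSE) {
  bp <- bin_pvalues(chip, control,
    pseudocount = pseudocount,
    background_floor = background_floor
  )
  all_p <- bp$p
  if (fdr) {
    adj <- stats::p.adjust(unlist(all_p, use.names = FALSE), method = "BH")
    all_p <- utils::relist(adj, all_p)
  }

  peaks <- list()
  for (cn in names(chip$counts)) {
    cc <- chip$counts[[cn]]
    lam <- bp$lambda[[cn]]
    p <- all_p[[cn]]
    sig <- which(p < p_cutoff & cc > lam)
    if (length(sig) == 0L) next
    grp <- cumsum(c(1L, diff(sig) > merge_gap_bins + 1L))
    for (g in unique(grp)) {
      b <- sig[grp == g]
      member <- seq(min(b), max(b)) # includes bridged gap bins
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = cn,
        start = (min(b) - 1L) * chip$bin_size,
        end = min(max(b) * chip$bin_size, chip$chrom_lengths[[cn]]),
        max_enrichment = max(cc[member] / lam[member]),
        p_value = min(p[member]),
        stringsAsFactors = FALSE
      )
    }
  }
  df <- if (length(peaks) > 0) do.call(rbind, peaks) else {
    data.frame(
      chrom = character(0), start = integer(0), end = integer(0),
      max_enrichment = numeric(0), p_value = numeric(0),
      stringsAsFactors = FALSE
    )
  }
  df <- df[order(match(df$chrom, names(chip$counts)), df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(
    list(
      peaks = df, bin_size = chip$bin_size, p_cutoff = p_cutoff,
      chrom_lengths = chip$chrom_lengths, n_nontelomeric = NA_integer_
    ),
    class = "peak_set"
  )
}

#' Per-bin expectations and Poisson p-values underlying the peak caller
#'
#' Computes, for every coverage bin, the control-derived expectation
#' `lambda = (control count + pseudocount) * chip library / control library`
#' (floored, by default, at the genome-wide scaled control rate) and the
#' upper-tail Poisson p-value of the chip count.
#'
#' @inheritParams call_peaks
#' @return List with per-chromosome `lambda` and `p` vectors.
#' @export
bin_pvalues <- function(chip, control, pseudocount = 0.5,
                        background_floor = TRUE) {
  stopifnot(inherits(chip, "coverage_track"), inherits(control, "coverage_track"))
  if (chip$bin_size != control$bin_size ||
    !identical(names(chip$counts), names(control$counts)) ||
    !all(lengths(chip$counts) == lengths(control$counts))) {
    stop("chip and control tracks must share genome and binning", call. = FALSE)
  }
  if (control$library_size <= 0) stop("control library is empty", call. = FALSE)
  if (pseudocount <= 0 && all(unlist(control$counts) == 0)) {
    stop("all-zero control with zero pseudocount: expectation undefined", call. = FALSE)
  }
  scale <- chip$library_size / control$library_size
  floor_lam <- if (background_floor) {
    (control$library_size / sum(lengths(control$counts)) + pseudocount) * scale
  } else {
    0
  }
  lambda <- lapply(names(chip$counts), function(cn) {
    pmax((control$counts[[cn]] + pseudocount) * scale, floor_lam)
  })
  names(lambda) <- names(chip$counts)
  p <- lapply(names(chip$counts), function(cn) {
    stats::ppois(chip$counts[[cn]] - 1L, lambda[[cn]], lower.tail = FALSE)
  })
  names(p) <- names(chip$counts)
  list(lambda = lambda, p = p)
}

#' Upper-tail Poisson p-value used by the peak caller
#'
#' `P(X >= count | lambda)` for a Poisson variate; exposed so the per-bin
#' model can be checked directly.
#'
#' @param count Observed bin count(s).
#' @param lambda Expected count(s).
#' @return Upper-tail probability, vectorized.
#' @export
poisson_tail_p <- function(count, lambda) {
  stats::ppois(count - 1L, lambda, lower.tail = FALSE)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf(
    "peak_set: %d peak(s) at p<%g%s\n", nrow(x$peaks), x$p_cutoff,
    if (is.na(x$n_nontelomeric)) "" else sprintf(" (%d nontelomeric)", x$n_nontelomeric)
  ))
  invisible(x)
}

#' Label peaks by genomic compartment and count nontelomeric ones
#'
#' Assigns each peak by midpoint position: inside a telomeric tract =>
#' `telomeric` (excluded from `n_nontelomeric`); inside a subtelomere window
#' => `subtelomeric`; otherwise `interstitial`. Intervals are half-open, so a
#' midpoint exactly on a tract/subtelomere boundary belongs to the
#' subtelomere.
#'
#' @param peakset A `peak_set`.
#' @param genome A `genome_model` carrying tract and subtelomere annotations,
#'   which must cover every chromosome peaks occur on.
#' @return The `peak_set` with a `label` column and `n_nontelomeric` filled
#'   in.
#' @export
classify_and_filter <- function(peakset, genome) {
  stopifnot(inherits(peakset, "peak_set"), inherits(genome, "genome_model"))
  df <- peakset$peaks
  bad <- setdiff(unique(df$chrom), genome$chrom)
  if (length(bad) > 0) {
    stop("peaks on unannotated chromosome(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  mid <- df$start + (df$end - df$start) %/% 2L
  in_iv <- function(iv) {
    vapply(seq_len(nrow(df)), function(i) {
      any(iv$chrom == df$chrom[i] & iv$start <= mid[i] & mid[i] < iv$end)
    }, logical(1))
  }
  label <- rep("interstitial", nrow(df))
  if (nrow(df) > 0) {
    label[in_iv(genome$subtelomeres)] <- "subtelomeric"
    label[in_iv(genome$tracts)] <- "telomeric"
  }
  df$label <- label
  peakset$peaks <- df
  peakset$n_nontelomeric <- sum(label != "telomeric")
  peakset
}

as_granges <- function(df) {
  GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Overlap between two peak sets
#'
#' A peak of `A` is shared iff it intersects at least 1 bp of any peak of
#' `B`; call with the arguments swapped for `B`'s perspective (the two
#' shared counts need not be equal).
#'
#' @param A,B `peak_set` objects on the same genome.
#' @return List with `n_A`, `n_B`, `n_shared` and `fraction_A_in_B`.
#' @export
overlap_sets <- function(A, B) {
  stopifnot(inherits(A, "peak_set"), inherits(B, "peak_set"))
  n_shared <- if (nrow(A$peaks) == 0 || nrow(B$peaks) == 0) {
    0L
  } else {
    sum(IRanges::overlapsAny(as_granges(A$peaks), as_granges(B$peaks)))
  }
  list(
    n_A = nrow(A$peaks), n_B = nrow(B$peaks), n_shared = n_shared,
    fraction_A_in_B = if (nrow(A$peaks) > 0) n_shared / nrow(A$peaks) else NA_real_
  )
}

#' Fold change of nontelomeric peak counts against a reference condition
#'
#' Ratios are reported raw (2 decimals) and rounded to the nearest integer
#' (half away from zero), the convention behind statements like "6- and
#' 15-fold more peaks".
#'
#' @param counts Named numeric vector of nontelomeric peak counts per
#'   condition.
#' @param reference Name of the reference condition (default: first element).
#' @return Data frame: condition, n_peaks, fold, fold_rounded.
#' @export
peak_fold_change <- function(counts, reference = names(counts)[1]) {
  if (is.null(names(counts))) stop("`counts` must be named by condition", call. = FALSE)
  ref <- counts[[reference]]
  if (is.na(ref) || ref <= 0) stop("reference peak count must be positive", call. = FALSE)
  fold <- counts / ref
  data.frame(
    condition = names(counts),
    n_peaks = as.integer(counts),
    fold = round(fold, 2),
    fold_rounded = as.integer(sign(fold) * floor(abs(fold) + 0.5)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Precision/recall of called peaks against the planted site catalog
#'
#' Precision: fraction of nontelomeric peaks intersecting (>= 1 bp) a planted
#' site. Recall: fraction of planted sites with occupancy at least
#' `min_occupancy` intersected by a nontelomeric peak.
#'
#' @param peakset A classified `peak_set` (see [classify_and_filter()]).
#' @param sites A `site_catalog` of planted ground truth.
#' @param min_occupancy Restrict recall to sites at least this strongly
#'   occupied.
#' @return List with `precision`, `recall`, `f1`, and the underlying counts.
#' @export
peak_recovery_stats <- function(peakset, sites, min_occupancy = 1) {
  stopifnot(inherits(peakset, "peak_set"))
  pk <- peakset$peaks
  if (!"label" %in% names(pk)) stop("classify the peak set first", call. = FALSE)
  pk <- pk[pk$label != "telomeric", , drop = FALSE]
  tr <- sites[sites$occupancy >= min_occupancy, , drop = FALSE]
  if (nrow(pk) == 0 || nrow(tr) == 0) {
    return(list(
      precision = NA_real_, recall = NA_real_, f1 = NA_real_,
      n_peaks = nrow(pk), n_sites = nrow(tr), n_hit_peaks = 0L, n_hit_sites = 0L
    ))
  }
  gp <- as_granges(pk)
  gs <- as_granges(tr)
  precision <- mean(IRanges::overlapsAny(gp, gs))
  recall <- mean(IRanges::overlapsAny(gs, gp))
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(
    precision = precision, recall = recall, f1 = f1,
    n_peaks = nrow(pk), n_sites = nrow(tr),
    n_hit_peaks = sum(IRanges::overlapsAny(gp, gs)),
    n_hit_sites = sum(IRanges::overlapsAny(gs, gp))
  )
}

#' Read a peak set written by [write_peaks_bed()]
#'
#' @param path BED6+ path (chrom, start, end, label, score, strand,
#'   enrichment, p).
#' @param genome A `genome_model` supplying chromosome lengths.
#' @param p_cutoff The cutoff the peaks were called at (metadata only).
#' @return A `peak_set` with labels restored.
#' @export
read_peaks_bed <- function(path, genome, p_cutoff = 1e-3) {
  if (length(readLines(path, n = 1L)) == 0L) {
    df <- data.frame(
      chrom = character(0), start = integer(0), end = integer(0),
      label = character(0), max_enrichment = numeric(0), p_value = numeric(0),
      stringsAsFactors = FALSE
    )
  } else {
    df <- read_bed(path, c(
      "chrom", "start", "end", "label", "score", "strand",
      "max_enrichment", "p_value"
    ))
  }
  structure(
    list(
      peaks = df[, c("chrom", "start", "end", "max_enrichment", "p_value", "label")],
      bin_size = NA_integer_, p_cutoff = p_cutoff,
      chrom_lengths = genome$length,
      n_nontelomeric = sum(df$label != "telomeric")
    ),
    class = "peak_set"
  )
}

#' Write a classified peak set as BED6+ (label, score, enrichment, p)
#'
#' Score is `-10 log10(p)` capped at 3000.
#'
#' @param peakset A `peak_set` (classified or not).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peakset, path) {
  df <- peakset$peaks
  score <- pmin(round(-10 * log10(pmax(df$p_value, 1e-300))), 3000)
  write_bed(data.frame(
    df$chrom, df$start, df$end,
    if ("label" %in% names(df)) df$label else ".",
    score, ".",
    signif(df$max_enrichment, 6), signif(df$p_value, 6),
    stringsAsFactors = FALSE
  ), path)
}
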