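#' Describe one experimental condition of the generation x genotype design
#'
#' A condition couples a telomerase-null generation (G0, G1, G3) and a RAP1
#' genotype (WT or KO) with the simulator knobs that emulate it: the relative
#' telomere length (`telomere_scale`), the number of planted subtelomeric and
#' interstitial binding sites, the end-distance decay of gradient-placed
#' sites, and the ChIP read-allocation fractions.
#'
#' The default ChIP allocation encodes the redistribution hypothesis: the
#' telomeric read mass is proportional to `telomere_scale`, and the protein
#' freed by tract shortening re-binds extratelomeric sites, so
#' `site_frac = site_frac_base + tel_frac * (1 - telomere_scale)` while the
#' background fraction stays constant across generations.
#'
#' @param generation One of `"G0"`, `"G1"`, `"G3"`.
#' @param rap1 `"WT"` or `"KO"`. KO samples yield background-only reads
#'   regardless of the site catalog.
#' @param telomere_scale Fraction in (0, 1] of the G0 telomere length;
#'   must be 1 for G0.
#' @param n_subtelomeric_sites,n_interstitial_sites Planted site counts.
#' @param n_interstitial_gradient How many interstitial sites follow the
#'   end-distance gradient; the remainder are placed uniformly (the
#'   "added" sites of later generations). Defaults to all of them for G0 and
#'   none otherwise.
#' @param gradient_decay Per-bp exponential decay rate of gradient placement
#'   probability with distance from the nearest chromosome end.
#' @param tel_frac Fraction of WT ChIP reads allocated to telomeric tracts at
#'   `telomere_scale = 1` (scales linearly with `telomere_scale`).
#' @param site_frac Fraction of WT ChIP reads allocated to planted sites;
#'   `NULL` applies the redistribution default above.
#' @param site_frac_base Site allocation at `telomere_scale = 1` used by the
#'   redistribution default.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(generation = c("G0", "G1", "G3"),
                           rap1 = c("WT", "KO"),
                           telomere_scale = 1,
                           n_subtelomeric_sites = 25L,
                           n_interstitial_sites = 15L,
                           n_interstitial_gradient = NULL,
                           gradient_decay = 1e-5,
                           tel_frac = 0.3,
                           site_frac = NULL,
                           site_frac_base = 0.4) {
  generation <- match.arg(generation)
  rap1 <- match.arg(rap1)
  if (!(telomere_scale > 0 && telomere_scale <= 1)) {
    stop("`telomere_scale` must lie in (0, 1]", call. = FALSE)
  }
  if (generation == "G0" && telomere_scale != 1) {
    stop("G0 is the reference generation: `telomere_scale` must be 1", call. = FALSE)
  }
  if (is.null(n_interstitial_gradient)) {
    n_interstitial_gradient <- if (generation == "G0") n_interstitial_sites else 0L
  }
  if (n_interstitial_gradient > n_interstitial_sites) {
    stop("`n_interstitial_gradient` cannot exceed `n_interstitial_sites`", call. = FALSE)
  }
  if (is.null(site_frac)) {
    site_frac <- site_frac_base + tel_frac * (1 - telomere_scale)
  }
  if (tel_frac * telomere_scale + site_frac >= 1) {
    stop("ChIP telomere + site allocation must leave room for background", call. = FALSE)
  }
  structure(
    list(
      generation = generation, rap1 = rap1,
      telomere_scale = telomere_scale,
      n_subtelomeric_sites = as.integer(n_subtelomeric_sites),
      n_interstitial_sites = as.integer(n_interstitial_sites),
      n_interstitial_gradient = as.integer(n_interstitial_gradient),
      gradient_decay = gradient_decay,
      tel_frac = tel_frac, site_frac = site_frac
    ),
    class = "condition_spec"
  )
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf(
    "condition_spec: %s / RAP1-%s | telomere_scale=%.2f | sites: %d subtel + %d interstitial (%d gradient) | decay=%g\n",
    x$generation, x$rap1, x$telomere_scale,
    x$n_subtelomeric_sites, x$n_interstitial_sites,
    x$n_interstitial_gradient, x$gradient_decay
  ))
  invisible(x)
}

#' Default generation x genotype condition matrix
#'
#' The study design emulated by the pipeline: telomere length 1 / 0.6 / 0.3
#' of G0 across generations, a fixed subtelomeric site complement, and
#' interstitial site counts growing roughly 6- and 15-fold (40 / 240 / 600
#' nontelomeric sites in total), with the added later-generation sites placed
#' uniformly along the arms. Each WT condition is paired with a matched KO.
#'
#' @param telomere_scales Named numeric vector of per-generation scales.
#' @param n_subtelomeric Subtelomeric site count (all generations).
#' @param n_interstitial Named integer vector of interstitial site counts.
#' @param gradient_decay Per-bp decay of G0-style gradient placement.
#' @return Named list of `condition_spec` objects
#'   (`G0_WT`, `G0_KO`, ..., `G3_KO`).
#' @export
default_condition_matrix <- function(telomere_scales = c(G0 = 1, G1 = 0.6, G3 = 0.3),
                                     n_subtelomeric = 25L,
                                     n_interstitial = c(G0 = 15L, G1 = 215L, G3 = 575L),
                                     gradient_decay = 1e-5) {
  if (is.unsorted(rev(telomere_scales))) {
    stop("telomere_scale must be non-increasing across G0, G1, G3", call. = FALSE)
  }
  out <- list()
  for (g in c("G0", "G1", "G3")) {
    for (r in c("WT", "KO")) {
      out[[paste(g, r, sep = "_")]] <- condition_spec(
        generation = g, rap1 = r,
        telomere_scale = telomere_scales[[g]],
        n_subtelomeric_sites = n_subtelomeric,
        n_interstitial_sites = n_interstitial[[g]],
        n_interstitial_gradient = min(n_interstitial[["G0"]], n_interstitial[[g]]),
        gradient_decay = gradient_decay
      )
    }
  }
  out
}
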