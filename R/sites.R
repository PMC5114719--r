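#' Plant a ground-truth binding-site catalog on a toy genome
#'
#' Places non-overlapping binding sites outside the telomeric tracts.
#' Subtelomeric sites fall uniformly within the subtelomere windows.
#' Interstitial sites come in two flavours mirroring the generational design:
#' "gradient" sites whose midpoint distance to the nearest chromosome end is
#' drawn with probability proportional to `exp(-gradient_decay * distance)`
#' (the G0 pattern of binding density decaying from the subtelomere toward the
#' chromosome centre), and "uniform" sites placed uniformly along the
#' interstitial space (the added sites of later generations that flatten the
#' profile).
#'
#' @param genome A `genome_model`.
#' @param condition A `condition_spec` giving site counts and decay.
#' @param seed Integer seed; the catalog is a deterministic function of
#'   (genome, condition, seed).
#' @param site_width Site width in bp.
#' @param occupancy Either a length-2 integer range from which per-site
#'   relative enrichment weights are drawn uniformly, or a single value
#'   assigned to every site. Weights must be >= 1.
#' @param max_tries Resampling attempts per site before declaring the packing
#'   infeasible.
#' @return A `site_catalog` data frame with columns chrom, start, end
#'   (0-based half-open), class (`subtelomeric`/`interstitial`) and occupancy,
#'   sorted by (chrom, start).
#' @export
plant_sites <- function(genome, condition, seed = 1L, site_width = 200L,
                        occupancy = c(2L, 8L), max_tries = 1000L) {
  stopifnot(inherits(genome, "genome_model"), inherits(condition, "condition_spec"))
  w <- as.integer(site_width)
  L <- genome$length[[1]]
  dom_start <- genome$tract_bp + genome$subtelomere_len # interstitial domain
  dom_end <- L - dom_start
  if (dom_end - dom_start < w) stop("no interstitial space for sites", call. = FALSE)

  n_sub <- condition$n_subtelomeric_sites
  n_grad <- condition$n_interstitial_gradient
  n_unif <- condition$n_interstitial_sites - n_grad

  with_seed(seed, {
    placed <- lapply(genome$chrom, function(x) matrix(numeric(0), ncol = 2))
    names(placed) <- genome$chrom
    ok_place <- function(cn, start) {
      end <- start + w
      m <- placed[[cn]]
      if (nrow(m) > 0 && any(start < m[, 2] & end > m[, 1])) return(FALSE)
      placed[[cn]] <<- rbind(m, c(start, end))
      TRUE
    }

    draw <- function(n, class, sampler) {
      out <- vector("list", n)
      for (i in seq_len(n)) {
        for (tries in seq_len(max_tries)) {
          cand <- sampler()
          if (cand$start >= 0 && cand$start + w <= L && cand$ok &&
            ok_place(cand$chrom, cand$start)) {
            out[[i]] <- data.frame(
              chrom = cand$chrom, start = cand$start,
              end = cand$start + w, class = class,
              stringsAsFactors = FALSE
            )
            break
          }
          if (tries == max_tries) {
            stop("infeasible site packing: resampling budget exhausted", call. = FALSE)
          }
        }
      }
      do.call(rbind, out)
    }

    subtel_sampler <- function() {
      win <- genome$subtelomeres[sample.int(nrow(genome$subtelomeres), 1L), ]
      start <- win$start + sample.int(win$end - win$start - w + 1L, 1L) - 1L
      list(chrom = win$chrom, start = start, ok = TRUE)
    }
    gradient_sampler <- function() {
      cn <- genome$chrom[sample.int(length(genome$chrom), 1L)]
      side <- sample(c("left", "right"), 1L)
      a <- dom_start + w / 2
      b <- L / 2
      lam <- condition$gradient_decay
      u <- stats::runif(1)
      d <- if (lam <= 0) {
        a + u * (b - a)
      } else {
        a - log(1 - u * (1 - exp(-lam * (b - a)))) / lam
      }
      mid <- if (side == "left") d else L - 1 - d
      start <- as.integer(round(mid - w / 2))
      list(chrom = cn, start = start, ok = start >= dom_start && start + w <= dom_end)
    }
    uniform_sampler <- function() {
      cn <- genome$chrom[sample.int(length(genome$chrom), 1L)]
      start <- dom_start + sample.int(dom_end - dom_start - w + 1L, 1L) - 1L
      list(chrom = cn, start = start, ok = TRUE)
    }

    parts <- list()
    if (n_sub > 0) parts$sub <- draw(n_sub, "subtelomeric", subtel_sampler)
    if (n_grad > 0) parts$grad <- draw(n_grad, "interstitial", gradient_sampler)
    if (n_unif > 0) parts$unif <- draw(n_unif, "interstitial", uniform_sampler)
    sites <- do.call(rbind, parts)
    if (is.null(sites)) {
      sites <- data.frame(
        chrom = character(0), start = integer(0), end = integer(0),
        class = character(0), stringsAsFactors = FALSE
      )
    }
    sites$occupancy <- if (nrow(sites) == 0) {
      numeric(0)
    } else if (length(occupancy) == 2L) {
      sample(seq(occupancy[1], occupancy[2]), nrow(sites), replace = TRUE)
    } else {
      rep(occupancy, nrow(sites))
    }
    if (nrow(sites) > 0 && any(sites$occupancy < 1)) {
      stop("site occupancy weights must be >= 1", call. = FALSE)
    }
    sites <- sites[order(match(sites$chrom, genome$chrom), sites$start), , drop = FALSE]
    rownames(sites) <- NULL
    class(sites) <- c("site_catalog", "data.frame")
    attr(sites, "condition") <- condition
    attr(sites, "seed") <- as.integer(seed)
    sites
  })
}

#' Write a site catalog as BED5 (class and occupancy in columns 4-5)
#'
#' @param sites A `site_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  write_bed(sites[, c("chrom", "start", "end", "class", "occupancy")], path)
}

#' Read a site catalog written by [write_sites_bed()]
#'
#' @param path BED path.
#' @return A `site_catalog` data frame.
#' @export
read_sites_bed <- function(path) {
  df <- read_bed(path, c("chrom", "start", "end", "class", "occupancy"))
  class(df) <- c("site_catalog", "data.frame")
  df
}
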