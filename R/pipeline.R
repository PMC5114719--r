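RUN_CONFIG_KEYS <- c(
  "genome", "conditions", "site", "depth", "read_length", "error_rate",
  "bin_size", "p_cutoff", "pseudocount", "merge_gap_bins", "n_profile_bins",
  "seed", "use_truth_alignments"
)
GENOME_KEYS <- c("n_chrom", "chrom_length", "telomere_units", "subtelomere_len")
CONDITION_KEYS <- c("telomere_scales", "n_subtelomeric", "n_interstitial", "gradient_decay")
SITE_KEYS <- c("width", "occupancy")

#' Default pipeline configuration
#'
#' The demo study conditions: a shared 3 x 1 Mb reference genome with 800
#' TTAGGG units per end and 25 kb subtelomeres; generations G0/G1/G3 at
#' telomere scale 1/0.6/0.3 with 40/240/600 planted nontelomeric sites; one
#' wild-type ChIP, one matched knockout ChIP and one matched input per
#' generation at 1e5 reads each; 200 bp coverage bins and a 1e-3 Poisson peak
#' cutoff.
#'
#' @param seed Base integer seed from which all per-sample seeds derive.
#' @param depth Reads per sample.
#' @param use_truth_alignments Use recorded sampling positions instead of the
#'   exact-match mapper (faster; appropriate when the mapper itself is not
#'   under study).
#' @return A validated config list.
#' @export
default_run_config <- function(seed = 1L, depth = 1e5, use_truth_alignments = FALSE) {
  validate_run_config(list(
    genome = list(
      n_chrom = 3L, chrom_length = 1e6, telomere_units = 800L,
      subtelomere_len = 25000L
    ),
    conditions = list(
      telomere_scales = c(G0 = 1, G1 = 0.6, G3 = 0.3),
      n_subtelomeric = 25L,
      n_interstitial = c(G0 = 15L, G1 = 215L, G3 = 575L),
      gradient_decay = 1e-5
    ),
    site = list(width = 200L, occupancy = c(2L, 8L)),
    depth = depth, read_length = 50L, error_rate = 0,
    bin_size = 200L, p_cutoff = 1e-3, pseudocount = 0.5, merge_gap_bins = 1L,
    n_profile_bins = 20L, seed = as.integer(seed),
    use_truth_alignments = use_truth_alignments
  ))
}

#' Validate a pipeline configuration (fail-fast on unknown keys)
#'
#' @param config Config list.
#' @return The config, invisibly valid.
#' @export
validate_run_config <- function(config) {
  chk <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra) > 0) {
      stop(sprintf("unknown %s key(s): %s", where, paste(extra, collapse = ", ")),
        call. = FALSE
      )
    }
    missing <- setdiff(allowed, names(x))
    if (length(missing) > 0) {
      stop(sprintf("missing %s key(s): %s", where, paste(missing, collapse = ", ")),
        call. = FALSE
      )
    }
  }
  chk(config, RUN_CONFIG_KEYS, "config")
  chk(config$genome, GENOME_KEYS, "genome config")
  chk(config$conditions, CONDITION_KEYS, "conditions config")
  chk(config$site, SITE_KEYS, "site config")
  scales <- unlist(config$conditions$telomere_scales)
  if (is.unsorted(rev(scales))) {
    stop("telomere_scales must be non-increasing across generations", call. = FALSE)
  }
  if (is.null(config$seed) || is.na(config$seed)) {
    stop("an explicit integer seed is required (no wall-clock seeding)", call. = FALSE)
  }
  config
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the defaults; unknown keys are rejected.
#'
#' @param path YAML path.
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  config <- default_run_config()
  for (k in names(y)) {
    if (!k %in% RUN_CONFIG_KEYS) stop("unknown config key: ", k, call. = FALSE)
    if (is.list(config[[k]]) && !is.null(names(config[[k]]))) {
      for (k2 in names(y[[k]])) {
        if (!k2 %in% names(config[[k]])) {
          stop(sprintf("unknown config key: %s$%s", k, k2), call. = FALSE)
        }
        v <- y[[k]][[k2]]
        config[[k]][[k2]] <- if (is.list(v)) unlist(v) else v
      }
    } else {
      config[[k]] <- y[[k]]
    }
  }
  validate_run_config(config)
}

#' Run the full simulate / quantify / map / call / profile pipeline
#'
#' Builds the shared reference genome, plants a per-generation site catalog,
#' simulates the wild-type ChIP, matched knockout ChIP and matched input for
#' every generation, computes the raw-read telomeric enrichment table
#' (normalized to input, then to the G0 wild type), calls peaks wild type
#' versus knockout, labels and counts nontelomeric peaks with fold changes
#' against G0, overlaps the generations' peak sets pairwise, and computes
#' distance-from-end density profiles with gradient statistics. Fixed seeds
#' make the whole run deterministic.
#'
#' @param config Configuration from [default_run_config()] or
#'   [read_run_config()].
#' @param outdir Optional output directory; when given, every stage's output
#'   is persisted (FASTA/BED/FASTQ/BEDGraph/TSV and a JSON report).
#' @param quiet Suppress per-stage progress messages.
#' @return A `run_report` list: `telomeric_table`, `peak_table`,
#'   `overlap_table`, `profile_stats` (+ per-generation `profiles`,
#'   `peaksets`, `sites`, the `genome`, and `provenance`).
#' @export
run_pipeline <- function(config = default_run_config(), outdir = NULL,
                         quiet = FALSE) {
  validate_run_config(config)
  persist <- !is.null(outdir)
  if (persist) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
    say("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }
  seed <- as.integer(config$seed)
  gens <- names(config$conditions$telomere_scales)

  genome <- stage("genome", build_genome(
    n_chrom = config$genome$n_chrom,
    chrom_length = config$genome$chrom_length,
    telomere_units = config$genome$telomere_units,
    subtelomere_len = config$genome$subtelomere_len,
    seed = derive_seed(seed, 0L)
  ))
  if (persist) write_genome(genome, outdir)

  conditions <- default_condition_matrix(
    telomere_scales = unlist(config$conditions$telomere_scales),
    n_subtelomeric = config$conditions$n_subtelomeric,
    n_interstitial = unlist(config$conditions$n_interstitial),
    gradient_decay = config$conditions$gradient_decay
  )

  sites <- list()
  samples <- list()
  for (i in seq_along(gens)) {
    g <- gens[i]
    wt <- conditions[[paste0(g, "_WT")]]
    ko <- conditions[[paste0(g, "_KO")]]
    sites[[g]] <- stage(
      paste0("sites_", g),
      plant_sites(genome, wt,
        seed = derive_seed(seed, 10L + i),
        site_width = config$site$width, occupancy = config$site$occupancy
      )
    )
    if (persist) write_sites_bed(sites[[g]], file.path(outdir, paste0("sites_", g, ".bed")))
    samples[[paste0(g, "_WT_chip")]] <- stage(
      paste0("sim_", g, "_WT_chip"),
      simulate_sample(genome, sites[[g]], wt, "chip",
        depth = config$depth,
        seed = derive_seed(seed, 20L + i), error_rate = config$error_rate,
        read_length = config$read_length
      )
    )
    samples[[paste0(g, "_KO_chip")]] <- stage(
      paste0("sim_", g, "_KO_chip"),
      simulate_sample(genome, sites[[g]], ko, "chip",
        depth = config$depth,
        seed = derive_seed(seed, 30L + i), error_rate = config$error_rate,
        read_length = config$read_length
      )
    )
    samples[[paste0(g, "_input")]] <- stage(
      paste0("sim_", g, "_input"),
      simulate_sample(genome, sites[[g]], wt, "input",
        depth = config$depth,
        seed = derive_seed(seed, 40L + i), error_rate = config$error_rate,
        read_length = config$read_length
      )
    )
  }
  if (persist) {
    for (nm in names(samples)) {
      write_fastq(samples[[nm]], file.path(outdir, paste0(nm, ".fastq")))
    }
  }

  tel_table <- stage("telomeric_content", {
    counts <- lapply(samples, count_telomeric_reads)
    pairs <- data.frame(
      sample = c(paste0(gens, "_WT_chip"), paste0(gens, "_KO_chip")),
      input = rep(paste0(gens, "_input"), 2L),
      stringsAsFactors = FALSE
    )
    telomeric_report(counts, pairs, reference = paste0(gens[1], "_WT_chip"))
  })

  peaksets <- list()
  profiles <- list()
  for (g in gens) {
    aln <- stage(paste0("align_", g), {
      lapply(samples[paste0(g, c("_WT_chip", "_KO_chip"))], function(rs) {
        if (isTRUE(config$use_truth_alignments)) {
          alignments_from_truth(rs, genome)
        } else {
          map_reads(rs, genome)
        }
      })
    })
    if (persist) {
      write_alignments_bed(aln[[1]], file.path(outdir, paste0(g, "_WT_chip.aln.bed")))
      write_alignments_bed(aln[[2]], file.path(outdir, paste0(g, "_KO_chip.aln.bed")))
    }
    cov <- lapply(aln, bin_coverage, bin_size = config$bin_size)
    if (persist) {
      write_bedgraph(cov[[1]], file.path(outdir, paste0(g, "_WT_chip.bedgraph")))
      write_bedgraph(cov[[2]], file.path(outdir, paste0(g, "_KO_chip.bedgraph")))
    }
    peaksets[[g]] <- stage(paste0("peaks_", g), {
      ps <- call_peaks(cov[[1]], cov[[2]],
        p_cutoff = config$p_cutoff,
        pseudocount = config$pseudocount,
        merge_gap_bins = config$merge_gap_bins
      )
      classify_and_filter(ps, genome)
    })
    if (persist) write_peaks_bed(peaksets[[g]], file.path(outdir, paste0(g, "_peaks.bed")))
    profiles[[g]] <- distance_profile(peaksets[[g]], genome, n_bins = config$n_profile_bins)
    if (persist) write_profile_tsv(profiles[[g]], file.path(outdir, paste0(g, "_profile.tsv")))
  }

  peak_counts <- vapply(peaksets, function(p) p$n_nontelomeric, integer(1))
  peak_table <- peak_fold_change(peak_counts, reference = gens[1])

  ov <- list()
  for (a in gens) {
    for (b in gens) {
      if (a == b) next
      o <- overlap_sets(peaksets[[a]], peaksets[[b]])
      ov[[length(ov) + 1L]] <- data.frame(
        A = a, B = b, n_A = o$n_A, n_B = o$n_B, n_shared = o$n_shared,
        fraction_A_in_B = o$fraction_A_in_B, stringsAsFactors = FALSE
      )
    }
  }
  overlap_table <- do.call(rbind, ov)

  profile_stats <- do.call(rbind, lapply(gens, function(g) {
    st <- gradient_stats(profiles[[g]])
    data.frame(
      generation = g, trend_corr = st$trend_corr,
      subtel_ratio = st$subtel_ratio, evenness_cv = st$evenness_cv,
      stringsAsFactors = FALSE
    )
  }))

  report <- structure(
    list(
      schema = "rap1shift-report/1",
      telomeric_table = tel_table,
      peak_table = peak_table,
      overlap_table = overlap_table,
      profile_stats = profile_stats,
      profiles = profiles,
      peaksets = peaksets,
      sites = sites,
      genome = genome,
      provenance = list(
        seed = seed,
        config = config,
        package_version = as.character(utils::packageVersion("rap1shift")),
        r_version = R.version.string
      )
    ),
    class = "run_report"
  )

  if (persist) {
    utils::write.table(tel_table, file.path(outdir, "telomeric_content.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(peak_table, file.path(outdir, "peak_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(overlap_table, file.path(outdir, "peak_overlaps.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(profile_stats, file.path(outdir, "profile_stats.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    payload <- list(
      schema = report$schema,
      telomeric_table = tel_table,
      peak_table = peak_table,
      overlap_table = overlap_table,
      profile_stats = profile_stats,
      provenance = report$provenance
    )
    jsonlite::write_json(payload, file.path(outdir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (", x$schema, ")\n\nTelomeric content (raw reads, input-normalized):\n", sep = "")
  print(x$telomeric_table, row.names = FALSE)
  cat("\nNontelomeric peak counts:\n")
  print(x$peak_table, row.names = FALSE)
  cat("\nDensity-profile statistics:\n")
  print(x$profile_stats, row.names = FALSE)
  invisible(x)
}
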