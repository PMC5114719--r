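#!/usr/bin/env Rscript
# Stage 1: build the toy reference genome and simulate the G0/G1/G3 x WT/KO
# ChIP-seq read sets with planted ground truth.
#
# Writes genome FASTA, ground-truth BEDs, per-generation site catalogs and
# nine FASTQ files (WT ChIP, KO ChIP, input per generation) to results/demo/.

suppressPackageStartupMessages(library(rap1shift))

outdir <- "results/demo"
cfg <- read_run_config(system.file("extdata", "demo_config.yaml", package = "rap1shift"))
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- build_genome(
  n_chrom = cfg$genome$n_chrom, chrom_length = cfg$genome$chrom_length,
  telomere_units = cfg$genome$telomere_units,
  subtelomere_len = cfg$genome$subtelomere_len,
  seed = rap1shift:::derive_seed(cfg$seed, 0L)
)
write_genome(genome, outdir)
print(genome)

conds <- default_condition_matrix(
  telomere_scales = cfg$conditions$telomere_scales,
  n_subtelomeric = cfg$conditions$n_subtelomeric,
  n_interstitial = cfg$conditions$n_interstitial,
  gradient_decay = cfg$conditions$gradient_decay
)

gens <- names(cfg$conditions$telomere_scales)
for (i in seq_along(gens)) {
  g <- gens[i]
  wt <- conds[[paste0(g, "_WT")]]
  ko <- conds[[paste0(g, "_KO")]]
  sites <- plant_sites(genome, wt,
    seed = rap1shift:::derive_seed(cfg$seed, 10L + i),
    site_width = cfg$site$width, occupancy = cfg$site$occupancy
  )
  write_sites_bed(sites, file.path(outdir, paste0("sites_", g, ".bed")))
  cat(sprintf(
    "%s: planted %d sites (%d subtelomeric, %d interstitial), telomere scale %.1f\n",
    g, nrow(sites), sum(sites$class == "subtelomeric"),
    sum(sites$class == "interstitial"), wt$telomere_scale
  ))
  write_fastq(
    simulate_sample(genome, sites, wt, "chip", cfg$depth,
      seed = rap1shift:::derive_seed(cfg$seed, 20L + i)
    ),
    file.path(outdir, paste0(g, "_WT_chip.fastq"))
  )
  write_fastq(
    simulate_sample(genome, sites, ko, "chip", cfg$depth,
      seed = rap1shift:::derive_seed(cfg$seed, 30L + i)
    ),
    file.path(outdir, paste0(g, "_KO_chip.fastq"))
  )
  write_fastq(
    simulate_sample(genome, sites, wt, "input", cfg$depth,
      seed = rap1shift:::derive_seed(cfg$seed, 40L + i)
    ),
    file.path(outdir, paste0(g, "_input.fastq"))
  )
}
cat(sprintf(
  "Simulated %d samples of %g reads each into %s\n",
  3 * length(gens), cfg$depth, outdir
))
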