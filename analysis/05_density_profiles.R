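#!/usr/bin/env Rscript
# Stage 5: peak density as a function of distance from the chromosome end.
#
# In G0 the binding density is highest in the subtelomeric strata and decays
# toward the chromosome centre; with shortened telomeres (G1, G3) the profile
# flattens as binding redistributes to interstitial sites. Writes
# per-generation profile TSVs and profile_stats.tsv.

suppressPackageStartupMessages(library(rap1shift))

outdir <- "results/demo"
gens <- c("G0", "G1", "G3")
genome <- load_genome(
  file.path(outdir, "genome.fa"),
  file.path(outdir, "telomere_tracts.bed"),
  file.path(outdir, "subtelomeres.bed")
)

stats_tab <- list()
for (g in gens) {
  ps <- read_peaks_bed(file.path(outdir, paste0(g, "_peaks.bed")), genome)
  prof <- distance_profile(ps, genome, n_bins = 20L)
  write_profile_tsv(prof, file.path(outdir, paste0(g, "_profile.tsv")))
  st <- gradient_stats(prof)
  stats_tab[[g]] <- data.frame(
    generation = g, trend_corr = st$trend_corr,
    subtel_ratio = st$subtel_ratio, evenness_cv = st$evenness_cv
  )
}
stats_tab <- do.call(rbind, stats_tab)
write.table(stats_tab, file.path(outdir, "profile_stats.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
print(stats_tab, row.names = FALSE)

g0 <- stats_tab[stats_tab$generation == "G0", ]
g3 <- stats_tab[stats_tab$generation == "G3", ]
cat(sprintf(
  "\nSubtelomeric density advantage drops from %.1fx (G0) to %.1fx (G3) and the\nprofile becomes more even (CV %.2f -> %.2f): binding redistributes away from\nthe chromosome ends as telomeres shorten.\n",
  g0$subtel_ratio, g3$subtel_ratio, g0$evenness_cv, g3$evenness_cv
))
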