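#!/usr/bin/env Rscript
# Stage 3: exact-match mapping of the ChIP and KO reads and 200-bp coverage
# tracks. Telomeric-tract reads are multimapped and drop out here, which is
# why stage 2 quantified them on the raw reads.
#
# Writes per-sample alignment BED and BEDGraph files to results/demo/.

suppressPackageStartupMessages(library(rap1shift))

outdir <- "results/demo"
genome <- load_genome(
  file.path(outdir, "genome.fa"),
  file.path(outdir, "telomere_tracts.bed"),
  file.path(outdir, "subtelomeres.bed")
)

for (g in c("G0", "G1", "G3")) {
  for (s in c("_WT_chip", "_KO_chip")) {
    id <- paste0(g, s)
    reads <- read_fastq(file.path(outdir, paste0(id, ".fastq")))
    aln <- map_reads(reads, genome)
    cat(sprintf(
      "%s: %d mapped, %d multimapped (discarded, mostly telomeric), %d unmapped\n",
      id, aln$n_mapped, aln$n_multimapped, aln$n_unmapped
    ))
    write_alignments_bed(aln, file.path(outdir, paste0(id, ".aln.bed")))
    write_bedgraph(bin_coverage(aln, bin_size = 200L),
      file.path(outdir, paste0(id, ".bedgraph"))
    )
  }
}
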