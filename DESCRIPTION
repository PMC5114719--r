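Package: rap1shift
Title: Simulated ChIP-seq Analysis of RAP1 Redistribution with Telomere Shortening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse the genome-wide redistribution of the
    shelterin subunit RAP1 as telomeres shorten across successive
    telomerase-null generations. Provides a synthetic read simulator with
    planted ground truth (telomeric tracts, subtelomeric and interstitial
    binding sites, knockout and input controls), an alignment-free telomeric
    repeat-read statistic with input normalization, a deterministic exact-match
    toy read mapper with binned coverage tracks, a Poisson per-bin peak caller
    against matched knockout controls with telomeric-peak exclusion,
    peak-set overlap and fold-change summaries, and peak-density profiles as a
    function of distance from the chromosome end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    BiocGenerics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
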