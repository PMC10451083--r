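Package: pedsweep
Title: Pedigree-Breeding Genome Analysis: IBD Tracing, Selective-Sweep
    Scans and QTL Mapping for Biparental Maize Panels
Version: 0.1.0
Authors@R:
    person("pedsweep", "developers", email = "pedsweep@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how pedigree breeding from a biparental
    cross reshapes a crop genome.  Traces each descendant inbred line's
    genome to its parent of origin and calls IBD-conserved regions (ICRs);
    scans the panel for selective sweeps with nucleotide diversity,
    Tajima's D and a composite-likelihood-ratio statistic in sliding
    windows; maps additive QTLs in a doubled-haploid population by
    inclusive composite interval mapping with moisture-corrected
    phenotypes; and co-localizes ICRs, sweep regions, QTLs and gene
    annotations by interval algebra.  Ships a forward simulator of
    two-parent breeding (recombination, truncation selection, DH
    populations, multi-environment phenotypes) with recorded ground truth
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
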