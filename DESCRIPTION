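Package: plastinet
Title: Phenotypically Plastic miRNAs, Transcripts and Histone Marks in a
    Mating-by-Age Factorial Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-alignment analysis of phenotypic plasticity in female
    Drosophila across a two-by-two mating-by-age design: permutation
    one-way ANOVA on quantile-normalized abundances with
    Benjamini-Yekutieli false discovery control and pooled-standard-
    deviation post hoc gating; ChIP-seq peak merging, FPKM quantification
    and median-background correction; small-RNA read-length profiling and
    calling of mating-specific degradation-fragment source genes;
    mating-induced accelerated-aging marker logic; and construction of
    three-layer miRNA-target-partner regulatory networks with histone-mark
    overlay. Includes a synthetic-data generator with planted ground truth
    so that every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    limma,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    rtracklayer,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
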