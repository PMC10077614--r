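Package: germvar
Title: Detection Programs for Clinical Whole-Genome Sequencing of Genetic Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bespoke variant-detection programs used around a clinical
    whole-genome-sequencing pipeline for genetic disorders: raw-read and
    coverage quality control, binomial allele-fraction models for
    per-chromosome aneuploidy and genome-wide triploidy calling, maximum
    likelihood estimation of foreign-DNA (maternal cell) contamination from
    variant allele fractions, sliding-window absence-of-heterozygosity
    detection with terminal-region reporting, paralog-aware SMN1/SMN2 copy
    number calling for spinal muscular atrophy, hidden-Markov-model
    segmentation of GC-corrected read-depth ratios with genotype assignment
    against known alpha-thalassemia deletion alleles, trio segregation
    filtering, and per-class sensitivity/specificity validation metrics.
    A deterministic synthetic-data generator emulates every input so the
    complete detection surface can be exercised without patient genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    jsonlite,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
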