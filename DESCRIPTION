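Package: thinqtl
Title: QTL Mapping in F2 Populations from Shallow Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantitative-genetics workflow for biparental F2
    populations genotyped by very low coverage (~0.1-0.2x) whole-genome
    sequencing. Includes two-tier variant quality filtering of parental
    SNP calls (a hard soft-filter expression plus an automated filter
    based on Gaussian fits to quality annotations), hidden-Markov-model
    reconstruction of F2 genotype segments and crossovers from sparse
    allele counts, assembly of crossover-derived marker matrices with
    population-level quality control, Haley-Knott regression genome scans
    with permutation thresholds, two-locus scans and stepwise
    penalized-LOD multiple-QTL model selection, and phenotype statistics
    for replicated flowering-time designs (broad-sense heritability,
    vernalization sensitivity, expression-based mutant classification,
    delta-delta-Ct quantification, pairwise contrasts and rosette growth
    trajectory analysis). A bundled synthetic-data generator simulates
    every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
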