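Package: structgwas
Title: Structured Genotype Simulation and Mixed-Model Association Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for genetic association studies
    under population and family structure. Simulates genotypes from a
    one-dimensional admixture model, from random admixed pedigrees with
    assortative mating, and from subpopulation trees with Balding-Nichols
    allele-frequency drift; fits subpopulation trees to coancestry estimates
    by WPGMA clustering and non-negative least squares; estimates kinship with
    the standard, bias-corrected and KING-robust estimators; simulates
    quantitative traits with exact narrow-sense heritability under fixed
    effect-size and random-coefficient models; runs principal-component and
    linear mixed-model association scans natively (REML null fit plus score
    test); and scores p-value calibration (signed RMSD of null p-values) and
    causal-locus classification (area under the precision-recall curve).
    Includes PLINK 1 BED/BIM/FAM readers and writers and an experiment driver
    for replicated model comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
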