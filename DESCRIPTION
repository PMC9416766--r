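Package: herdtrend
Title: Quantitative Genetic Evaluation of Dairy Cattle Fertility and
    Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-trait quantitative-genetic analysis of dairy cattle
    breeding data on simulated populations: gene-dropping simulation of
    pedigrees, breeding values, phenotypes, insemination sequences and
    SNP genotypes; pedigree algebra (inbreeding, numerator relationship
    matrix and its sparse inverse, unknown-parent groups); derived
    fertility and longevity traits (conception status with geometric
    imputation of censored records, projected herd-life,
    herd-year-season classes); multi-trait animal-model BLUP with
    reliabilities, genetic-base rebasing and realized genetic trends;
    multi-trait REML variance components (EM and average-information
    updates) with derived heritabilities and correlations; selection
    index theory (index fractions, expected genetic gains, total
    economic gain, intensity calibration); and mixed-model genome-wide
    association with IBS kinship, pseudo-heritability and cross-trait
    marker-effect comparison. Ships the published Israeli Holstein
    breeding-index weights and first-parity variance components as
    reference parameter sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Matrix, survival
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
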