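Package: kinlod
Title: Close-Kin Inference from Microsatellite Genotypes via LOD Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Pairwise kinship inference for diploid microsatellite data
    using log-odds (LOD) likelihood-ratio scores under a per-allele
    genotyping-error model. Implements genotype-pair likelihoods for
    parent-offspring, full-sibling, second-degree and self/monozygotic
    hypotheses via Cotterman identity-by-descent coefficients,
    Monte-Carlo calibration of LOD cut-offs with expected false-positive
    and false-negative accounting, duplicate/resample detection,
    maximum-likelihood kinship classification with mitochondrial
    haplotype and sex consistency annotation, triad assembly, and tests
    of geographical aggregation of close kin (rank-sum test on longitude
    differences and tail quantile regression of LOD scores). Includes a
    pedigree-based simulator of survey-style biopsy datasets for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
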