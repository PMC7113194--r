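Package: longherit
Title: SNP Heritability of Longitudinal Trait Averages and Changes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates SNP-based heritability of per-subject phenotypic
    averages (B0) and longitudinal changes (B1) from repeated-measure
    cohort data. Subject trajectories are derived by a two-stage
    regression that weights each visit by the inverse of its
    period-specific residual variance; heritability is then estimated by
    average-information REML on a genetic relationship matrix, overall
    and partitioned by chromosome, with likelihood-ratio tests under the
    boundary chi-square mixture null. Includes trajectory GWAS with
    principal-component covariates and Benjamini-Hochberg FDR utilities,
    PLINK bed/bim/fam and GCTA GRM binary input/output, genotype quality
    control, and a synthetic-cohort generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
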