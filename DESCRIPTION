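Package: magicgs
Title: Genomic Selection and Association Analysis for MAGIC Populations
    Under Water Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection in multi-parent advanced generation
    inter-cross (MAGIC) populations evaluated under water stress. Provides
    genotype handling (VCF and dosage-matrix import, MAF filtering, distance
    thinning, VanRaden genomic relationship matrix), derivation of drought
    phenotypes (water content, growth against destructive baselines, organ
    aggregates), GBLUP with additive and residual genetic effects fitted by
    average-information REML, Cullis heritabilities and genetic coefficients
    of variation, a general-linear-model GWAS with principal-component
    covariates and LD-based delimitation of associated regions, the
    Smith-Hazel genomic selection index, leave-one-out and repeated k-fold
    cross-validation of predictive ability and accuracy, prediction of
    unphenotyped lines, and a MAGIC population simulator with a known truth
    set for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
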