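Package: svdgp
Title: Reduced-Dimension Genomic Prediction via Singular Value Decomposition
Version: 0.1.0
Authors@R: person("svdgp", "maintainers", email = "maintainers@svdgp.org", role = c("aut", "cre"))
Description: Genomic prediction from SNP dosage data using singular value
    decomposition of the genotype matrix. Implements principal component
    ridge regression (full, core-sample reduced, two-stage and
    chromosome-wise variants), SNP-BLUP and GBLUP solvers, and exact
    Woodbury-identity inverses of principal-component-approximated genomic
    relationship matrices (PCIG, QRIG, weighted forms) together with an APY
    baseline, a forward Wright-Fisher genotype/phenotype simulator with
    bottleneck demography, and a model-comparison harness for
    core-sample/validation designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
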