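Package: twinvolve
Title: Quantitative Genetic Analysis of Twin-Family Volumetric and
    Behavioral Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative genetic analysis of twin-family
    phenotype data, motivated by studies of cerebellar volumes and
    cognition in extended twin designs. Provides a synthetic twin-cohort
    generator with known additive genetic (A), shared environmental (C)
    and unique environmental (E) variance structure; conversion of
    individual-wise tables to family-wise records with relatedness
    coefficients; a phenotypic stage with covariate-adjusted
    brain-behavior regressions, correlation matrices and
    Benjamini-Hochberg false discovery rate control; univariate ACE
    structural models fitted by full-information maximum likelihood with
    profile-likelihood confidence intervals and boundary-corrected
    mixture chi-square likelihood-ratio tests; and bivariate Cholesky
    decompositions yielding genetic and environmental correlations and
    their contributions to phenotypic covariance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
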