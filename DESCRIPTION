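Package: ssdGP
Title: Training Set Sample Size Determination for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Determines a cost-effective training set sample size for genomic
    prediction from genotypes alone. Training sets are optimized under the
    r-score criterion over a grid of sizes, an S-shaped (logistic or
    Weibull-type) growth curve is fitted to the r-score versus size profile,
    and the relative operating curve RErs is inverted at target relative
    accuracies to yield the recommended size. The procedure is validated with
    GBLUP prediction via Henderson's mixed-model equations and the relative
    prediction ability REpa. Includes marker quality control, principal
    component scores, a cluster-proportional sampling rule for structured
    populations, and a synthetic genotype/phenotype simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    withr,
    Rcpp,
    minpack.lm,
    jsonlite,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'config.R'
    'curves.R'
    'markers.R'
    'rscore.R'
    'optimizer.R'
    'pipeline.R'
    'simdata.R'
    'ssdGP-package.R'
    'validate.R'
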