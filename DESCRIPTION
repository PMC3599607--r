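Package: bwsmethyl
Title: Age-Adjusted Nonparametric Detection of Differentially Methylated Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control testing of locus-wise DNA methylation beta-values with
    adjustment for age by stratification. Within each age group a one-sided
    Baumgartner-Weiss-Schindler (BWS) rank statistic compares the case and
    control empirical distributions; its null tail probability comes from a
    piecewise-exponential formula fitted to the permutation distribution (and
    refittable by permutation). Left- and right-sided p-values are combined
    across age groups with Fisher's method and the two-sided combined p-value is
    obtained from the maximum of the two chi-square statistics. Includes the
    combined t-test, combined Wilcoxon test and age-adjusted linear regression
    comparators, generative models for type-I-error and power simulation
    (three-component beta-value mixtures and beta-distribution scenarios), and a
    locus-wise pipeline for beta-value matrices with quality-control filtering,
    age binning and pseudo case-control splitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
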