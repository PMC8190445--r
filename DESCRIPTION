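Package: rohload
Title: Runs of Homozygosity, Mutation Load and Inbreeding Depression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying inbreeding depression through runs of
    homozygosity (ROH) on genetic-map coordinates. Implements windowed ROH
    detection on centimorgan positions, haplotype-age based length classes,
    per-class inbreeding coefficients (F_ROH), a forward Wright-Fisher
    simulator of deleterious and neutral mutation dynamics under a
    bottleneck-and-recovery demography, per-class mutation-load statistics,
    and binomial mixed models of first-year survival on class-specific
    inbreeding coefficients, with both MCMC and maximum-likelihood backends.
    Synthetic-data generators produce genotype fixtures with planted
    homozygous segments, linkage-map fixtures, and survival cohorts with
    known effect sizes for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    lme4,
    rjags,
    coda,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
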