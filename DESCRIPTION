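Package: isodiet
Title: Bayesian Stable-Isotope Diet Analysis with Individual Specialization Metrics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating consumer diet composition from bulk carbon and
    nitrogen stable isotope ratios. Implements temporal isotope corrections
    (Suess and Laws effects, bulk nitrogen restoration for lipid-extracted
    tissue), permutation multivariate statistics for prey-group differentiation
    (PERMANOVA with Manhattan or Euclidean distance, pairwise contrasts with
    Benjamini-Yekutieli adjustment, dispersion-based outlier screening), a
    Bayesian concentration-dependent mixing model with isometric log-ratio
    covariate structure (fixed class/year effects, individual random effects,
    multiplicative error), WAIC and Pareto-smoothed importance-sampling
    leave-one-out model comparison, an individual diet specialization index,
    inter-individual diet heterogeneity tests, and a seeded synthetic-data
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
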