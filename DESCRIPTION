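Package: decontamix
Title: Distribution-Based Contaminant Filtering for Low-Biomass Sorted Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes reagent and column background from low-biomass 16S count
    tables by estimating, for every sample, the mixture proportion of an
    averaged negative-control profile via least squares, subtracting it,
    clamping, renormalizing and rescaling read depth. Includes the downstream
    compositional toolkit used with antibody-sorted (e.g. IgG-bound) paired
    bronchoalveolar-lavage communities: additive log-ratio transforms, exact
    paired Wilcoxon tests, covariate-adjusted ALR-difference regression,
    Manhattan/Bray-Curtis distances, PERMANOVA with automatic exact
    enumeration, NMDS ordination, and log-log bacterial-load/cytokine
    association, plus a Dirichlet-multinomial cohort simulator with known
    contaminant admixture for validating every stage against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    permute
Config/testthat/edition: 3
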