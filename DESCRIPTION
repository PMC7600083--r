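Package: dietbiome
Title: Diet Quality, Usual Intake and Gut Microbiota Association Analysis
Version: 0.1.0
Authors@R:
    person("Vidarium", "Reanalysis Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline linking 24-hour dietary recall data to gut
    microbiota composition and diversity. Implements density-based diet
    quality scoring (an adapted Healthy Eating Index capped at 75 points, a
    70-point index based on the Colombian Food-Based Dietary Guidelines, and
    the percentage of calories from ultraprocessed foods), food-group and
    nutrient intake estimation with best-linear-unbiased-predictor (BLUP)
    shrinkage towards usual intake, OTU-table processing (rarefaction,
    Shannon-family alpha diversity, weighted and unweighted UniFrac), and an
    association layer (z-score PCA, multivariable adjustment, PERMANOVA,
    permutation Procrustes, and random-forest community selection with
    Spearman-signed output). Ships a synthetic-cohort generator with planted
    diet-to-OTU effects so that every stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
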