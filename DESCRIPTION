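Package: biomotif
Title: Mixed-Membership Species Motifs and Phylogenetic Beta Diversity for
    Presence-Absence Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits Bernoulli grade-of-membership (mixed-membership) models to
    binary site-by-species presence-absence matrices, yielding continuous
    per-site mixing proportions over latent species motifs (biotas) and
    per-motif species occurrence probabilities. Provides MAP-EM fitting with
    multi-restart initialization and BIC-based selection of the number of
    motifs, relative-contribution (eta) summaries and species classification,
    top distinguishing species per motif, phylogenetic beta-diversity
    statistics (unweighted UniFrac, Faith's phylogenetic diversity,
    richness-standardized PD, theta-weighted Bray-Curtis), phylogenetic
    time-slicing of species into lineages, a synthetic archipelago generator
    for end-to-end testing, pie-map and structure-plot visualizations, and a
    reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    picante,
    phangorn,
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
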