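Package: reefdiet
Title: Diet, Condition and Growth Analysis for Reef Fishes Across Habitat
    Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies dietary and performance responses of coral reef
    fishes to habitat degradation from tabular field and metabarcoding
    data. Implements Le Cren's relative condition factor with
    condition-by-habitat interaction models and bootstrapped log
    variance ratio (lnVR) contrasts, von Bertalanffy growth fitting with
    bootstrap comparison between habitat zones, Bray-Curtis community
    analysis (PCoA, NMDS, PERMANOVA with pairwise Bonferroni tests),
    Amundsen-Costello graphical feeding-strategy analysis, sample-based
    rarefaction, negative-binomial mixed models linking prey read
    abundance to coral cover, and shared survey statistics
    (Kruskal-Wallis with epsilon squared, Dunn's post hoc, ANOVA/Tukey,
    Shannon diversity, densities). A seed-reproducible synthetic data
    generator emulates the zone-structured sampling design so every
    stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    minpack.lm,
    glmmTMB,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
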