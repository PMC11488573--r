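Package: nfixpd
Title: Temporal Change in Nitrogen-Fixer Phylogenetic Diversity from
    Vegetation Resurveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify multi-decadal change in the diversity of
    nitrogen-fixing plants from paired (baseline/resurvey) vegetation
    plots. Computes community phylogenetic diversity (Faith's PD, mean
    pairwise distance, mean nearest taxon distance) on dated phylogenies
    with genus- and family-level grafting of unplaced species; derives
    per-plot change statistics and per-species fate statistics
    (lost/gained/conserved guilds, net plot-occupancy change); builds
    environmental change predictors (cumulative nitrogen deposition with
    an end-of-series clamp, 5-year moving-mean temperature and UNEP
    aridity-index change); fits random-intercept linear mixed models by
    profiled REML with standardized predictors and baseline covariates;
    tests phylogenetic signal in species fates with Pagel's lambda; and
    simulates complete synthetic study systems (Yule trees,
    clade-conserved fixer traits, site environmental trajectories,
    occupancy dynamics with deposition-dependent loss) with known ground
    truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    phytools,
    picante,
    car,
    jsonlite
Config/testthat/edition: 3
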