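Package: sulcalstrain
Title: Sulcal Strain Concentration from Simulated Head-Impact Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational injury-biomechanics pipeline linking
    head-impact kinematics to cortical strain at sulcal depths. Generates
    synthetic six-degree-of-freedom head kinematics for three player-position
    exposure profiles, drives an idealized sulcated finite-element brain
    cross-section (explicit dynamics, neo-Hookean brain and cerebrospinal
    fluid, prescribed rigid skull motion), extracts per-element peak
    maximum-principal Green-Lagrange strain and strain rate, rasterizes the
    fields to NIfTI volumes with a matching sulcal/gyral atlas, summarizes
    them per impact (whole-brain 90th percentile, region means), and runs the
    cohort statistics: paired sulci-versus-gyri comparison with effect size,
    one-way ANOVA with Tukey HSD across exposure profiles, two-way mixed
    repeated-measures ANOVA, Pearson correlations and multiple regression of
    sulcal strain on peak kinematics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    withr,
    jsonlite
Config/testthat/edition: 3
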