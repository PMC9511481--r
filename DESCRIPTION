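Package: ligandbias
Title: Ligand Bias Quantification from Kinetic Luminescence Recruitment Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of split-luciferase (NanoBiT-style) recruitment
    assays used to quantify functional selectivity of GPCR agonists. Raw kinetic
    time-luminescence plate traces are corrected for interwell variability,
    integrated to areas under the curve (AUC), solvent-subtracted, and normalized
    to a reference agonist; concentration-response data are fitted with a
    three-parameter logistic model with profile-likelihood confidence intervals;
    pathway-specific intrinsic relative activities (RAi) are combined into
    log10 bias factors with nonparametric significance testing (Kruskal-Wallis
    with Dunn post hoc comparisons); wild-type versus mutant receptor changes
    are summarized as potency fold-changes and efficacy drops; and qualitative
    bias plots (centered quadratic fits of equimolar responses) are produced.
    A seeded plate-shaped simulator generates synthetic studies with known
    ground truth so the full pipeline can be validated without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
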