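Package: msncable
Title: Passive Cable Modelling and Quantitative Electrophysiology of
    Striatal Projection Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative comparison of direct- (D1) and
    indirect-pathway (D2) medium spiny neurons: SWC morphology input/output
    with morphometry and Sholl analysis, passive compartmental modelling of
    reconstructed dendritic trees with a tree-structured Crank-Nicolson
    solver, frequency-dependent electrotonic analysis (inward/outward log
    attenuation and morphoelectrotonic transforms), double-exponential
    synapse simulation under somatic voltage clamp with EPSC detection and
    synaptic parameter fitting, extraction of intrinsic-membrane and action
    potential features from current-clamp recordings, dendritic spine
    sub-typing and glutamatergic apposition calling, the group-comparison
    statistical layer (normality-gated two-sample tests, two-way ANOVA with
    post hocs, bootstrap median confidence intervals, firing-rate linear
    models), and seeded synthetic-data generators that emulate the four
    experimental groups so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
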