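Package: tesuq
Title: Uncertainty Quantification of Transcranial Electrical Stimulation
    Fields on Synthetic Head Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates transcranial direct-current stimulation (tDCS) on
    seeded synthetic multi-shell head phantoms with white-matter-lesion
    inclusions and quantifies the uncertainty of the induced electric field
    under uncertain tissue conductivities.  Provides a first-order
    tetrahedral finite-element solver for the quasi-static volume-conductor
    problem with an analytic concentric-shell oracle, an adaptive
    generalized polynomial chaos surrogate of the electric-field magnitude
    over beta-distributed conductivities with coefficient-based moments and
    variance-based Sobol sensitivity indices, region-of-interest and
    electrode-to-electrode line summaries, and the nonparametric group
    statistics (Shapiro-Wilk gate, ANOVA or Kruskal-Wallis with Dunn
    post-hoc tests and eta-squared effect sizes) used to compare lesion-load
    groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
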