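Package: petref
Title: Data-Driven Reference Region Optimization for Dynamic Tau PET
Version: 0.1.0
Authors@R:
    person("petref", "developers", email = "petref@example.org", role = c("aut", "cre"))
Description: Tools for quantifying 4R-tau PET tracers without a predefined
    tissue reference: carotid image-derived input function (IDIF) extraction
    from dynamic PET via spatial independent component analysis, Logan
    graphical analysis of total distribution volume (VT), an iterative
    white-matter reference-region search that maximizes covariate-adjusted
    patient-versus-control discrimination in a target region, and downstream
    SUVr/VTr validation statistics (ANCOVA with Tukey adjustment and Cohen's
    d, ROC analysis with paired DeLong AUC comparison, severity regression,
    and permutation-based voxel-wise cluster inference). Includes a synthetic
    dynamic-PET phantom generator with known kinetic ground truth so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
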