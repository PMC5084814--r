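Package: chromamyelin
Title: Absolute-Pitch Scoring and Surface-Based Quantitative R1 Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying cortical myelin correlates of absolute pitch.
    Scores absolute-pitch test sessions with octave-error correction (absolute
    corrected error, AP score, hit rate, confusion matrices), converts
    quantitative T1 to R1 maps with bounding, smooths per-vertex maps on
    triangle meshes by iterated mass-conserving Gaussian diffusion to a target
    FWHM, fits vertex-wise general linear models with nuisance covariates, and
    performs random-field-theory cluster-level inference over a masked search
    region. Includes a Monte-Carlo assessment of effect-size estimation
    reliability under unbalanced, ethnicity-confounded group designs, and
    synthetic-data generators (meshes, subject tables, per-vertex maps with
    planted effects, trial-level behavioral responses) so the full pipeline
    runs end-to-end without any acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
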