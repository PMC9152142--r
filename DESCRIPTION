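Package: gmintegrity
Title: Latent Change Score Models of Gray-Matter Structural Integrity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multigroup latent change score modelling of latent gray-matter
    structural integrity factors measured by multimodal MRI indicators
    (voxel-based morphometry gray-matter probability, magnetization transfer
    saturation, and mean diffusivity), with cardiovascular fitness coupling.
    Provides a compact RAM-parameterized structural equation modelling kernel
    with full-information maximum likelihood estimation over missingness
    patterns, factorial invariance testing by likelihood-ratio ladders,
    one-sided directional inference, data-hygiene operators (intracranial
    volume adjustment, longitudinal standardization, univariate and
    Mahalanobis outlier screens, training-compliance classification),
    repeated-measures sensitivity/power computations, a synthetic-data
    generator with realistic exercise-intervention study structure, and an
    end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    withr,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
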