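Package: sealassoc
Title: At-Sea Association Analysis for Acoustically Tagged Grey Seals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and analyses at-sea associations among grey seals
    carrying acoustic transceivers and archival Fastloc GPS tags. Cleans
    acoustic detection logs, clusters detections into dyadic associations
    with a 30-minute gap rule, interpolates association locations from GPS
    tracks, discretises tracks into hourly time steps, classifies slow
    (area-restricted search) versus fast movement with a two-state hidden
    Markov model with exponential emissions, samples available habitat
    depths at kernel-density-weighted random locations, and compares depth
    and travel rate by association state with Gaussian mixed models with
    AR(1) residual correlation and a Williams-corrected G test of sex-pair
    composition. Includes a synthetic biologging data generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    nlme
Config/testthat/edition: 3
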