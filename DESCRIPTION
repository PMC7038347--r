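Package: ipdr
Title: Foot-Mounted Inertial Pedestrian Dead Reckoning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs indoor walking, jogging, and running trajectories
    from foot-mounted six-axis inertial measurement unit (IMU) recordings.
    Provides stride segmentation by subsequence dynamic time warping against
    per-activity gyroscope templates, adapted toe-off and mid-stance event
    detection, activity-aware zero-velocity detection, strapdown inertial
    navigation with an error-state complementary Kalman filter applying
    zero-velocity updates, stride-level trajectory metrics (return position
    error, strides out of trajectory, event F-scores), and a kinematically
    consistent synthetic gait-signal generator with full ground truth for
    testing every stage without real sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
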