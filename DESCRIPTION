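Package: hipload
Title: Patient-Specific Musculoskeletal Estimation and Validation of Hip Joint Forces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale musculoskeletal pipeline for estimating hip joint
    contact forces from motion-capture marker trajectories and force-plate
    data, and validating them against instrumented-prosthesis style in vivo
    recordings. Provides a simplified lower-limb model with selectable
    hip-joint-width source (marker-optimized or CT-measured), constant-strength
    and Hill-type muscle models, polynomial and min/max muscle-recruitment
    criteria solved per frame, a synthetic trial generator for one-leg stance
    and level walking with known ground truth, and the complete validation
    metric suite (peak-force-phase magnitude and angular deviations, component
    RMSE, correlation, Bland-Altman limits of agreement with nonparametric
    statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
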