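Package: reconarm
Title: Upper-Limb Musculoskeletal Models for Breast Reconstruction Variants
Version: 1.0.0
Authors@R: person("reconarm", "developers", role = c("aut", "cre"),
    email = "reconarm@example.org")
Description: Desk-scale musculoskeletal modeling engine for studying shoulder
    function after breast cancer surgery. Builds articulated upper-limb models
    for three surgical conditions (lumpectomy, subpectoral implant
    reconstruction, autologous flap reconstruction), including
    cylinder-obstacle muscle-path wrapping for a 405-cc implant, analytic
    stadium-solid torso mass properties with tissue-density substitution,
    static inverse-dynamics validation against cohort strength data, a
    simplified computed-muscle-control activation stage, and induced
    acceleration analysis of per-muscle contributions to hand acceleration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
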