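Package: heelstrike
Title: Heel-Strike Energy Absorption from Synchronized Force-Plate and
    Marker Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the mechanical energy absorbed by the foot-ankle
    system during the heel-strike phase of barefoot walking from
    synchronized force-plate and optical-marker recordings.  Reduces raw
    eight-channel force-plate signals to net ground reaction force and
    center of pressure, reconstructs a bone-fixed heel point from a
    two-marker lower-leg cluster, and computes the work done by the
    ground reaction force over the foot-ankle deformation (the
    force-integral method) alongside original and improved effective
    foot-mass models.  Includes per-subject and study-level aggregation
    with exact small-sample nonparametric method comparisons, a
    heel-point sensitivity analysis, and a viscoelastic heel-impact
    simulator with a full ground-truth energy audit for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
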