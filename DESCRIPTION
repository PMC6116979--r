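Package: spineadapt
Title: Coupled Intervertebral Disc Adaptation and Vertebral Bone
    Remodelling After Spinal Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulator of mechanoregulated adjacent-segment
    tissue changes after lumbar spinal fusion.  Couples an
    extracellular-matrix adaptation model of the intervertebral disc
    (cell-population and collagen/glycosaminoglycan dynamics driven by a
    biphasic mechanical stimulus built from deviatoric strain and fluid
    velocity) with site-specific, strain-energy-density driven bone
    remodelling of the neighbouring vertebra.  Includes Donnan osmotic
    swelling of the nucleus, a coarse linear poroelastic mechanics
    provider, seeded synthetic disc/vertebra fixtures, a semi-coupled
    macro/micro time-stepping scheduler, and the outcome operators used
    to compare predictions against follow-up density fields (spherical
    smoothing, minimal-detectable-change gating, per-element
    correlation, water-content to degeneration-grade translation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
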