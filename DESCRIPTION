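Package: mertbolus
Title: Modulated Electron Radiotherapy Bolus Design with 3D-Printable Output
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Iterative design of thickness-modulated electron-beam bolus for
    modulated electron radiation therapy (MERT). Ray lines are traced from the
    virtual source through a design grid; the gap between the distal 90%
    isodose surface and the distal surface of the planning target volume is
    converted to a shift of bolus thickness via a coefficient-of-equivalent-
    thickness (CET) line integral that accounts for tissue heterogeneity.
    Five regional modulation operators (hot-spot smoothing, coverage
    smoothing, irregular-surface smoothing, PTV-margin adjustment and
    outside-PTV extrusion) refine the thickness map, which is converted to a
    watertight, printable STL solid. Includes a documented broad-beam
    electron dose surrogate for desk-scale iteration, CET calibration from
    percentage-depth-dose curves, 2D gamma comparison, and synthetic phantom
    generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'io-volume.R'
    'io-structures.R'
    'io-pdd.R'
    'io-stl.R'
    'cet.R'
    'beam.R'
    'phantoms.R'
    'dose-surrogate.R'
    'gamma.R'
    'surface.R'
    'sbt.R'
    'modulation.R'
    'calibration.R'
    'mesh.R'
    'pipeline.R'
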