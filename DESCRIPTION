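Package: PediMorph
Title: Landmark-Based Brain and Head Morphometry, Volumetry and
    Growth-Trajectory Analysis for Pediatric Structural MRI
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring the developing head and brain on
    T1-weighted structural MRI: AC-PC landmark geometry and the seven
    classic landmark-based distance measures (brain length, width,
    height, AC-PC distance, head length, width, height); plane-cut head
    volumetry from the nasion/inion/preauricular reference planes;
    EM-based partial-volume tissue classification into gray matter,
    white matter and CSF; landmark-driven affine atlas registration with
    majority-vote label fusion; and the MANOVA (Wilks' lambda with Rao's
    approximate F), factorial GLM and quadratic peak-age machinery used
    to compare growth trajectories between cohorts.  A synthetic
    head-phantom generator with nested ellipsoidal tissue compartments
    and a cohort simulator with configurable growth models provide known
    ground truth for every stage, so the whole pipeline is testable
    without access to clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'PediMorph-package.R'
    'VolumeGrid.R'
    'landmarks.R'
    'phantom.R'
    'cohort.R'
    'fusion.R'
    'morphometry.R'
    'stats.R'
    'volumetry.R'
    'segmentation.R'
    'pipeline.R'
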