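Package: lvforce
Title: Global Left-Ventricular Hemodynamic Force from 4D Flow Velocity Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the global hemodynamic force that intraventricular blood
    exerts on the left-ventricular (LV) wall from time-resolved three-directional
    (4D flow) velocity fields. Pressure gradients are evaluated voxelwise from the
    Navier-Stokes momentum balance on a segmented, moving LV domain and integrated
    over the cavity per cardiac frame; the force vector is projected onto an
    anatomical long-axis/short-axis frame and summarized by diastolic
    force-direction metrics (SAx-max/LAx-max ratios per filling wave, time-averaged
    short-axis force, loop orientation, velocity-to-force peak lag). Includes
    phase-contrast preprocessing (temporal velocity unwrapping, polynomial
    background-offset removal), cardiac-phase detection from valve-plane speed
    traces, a self-validating synthetic LV phantom and cohort generator with
    healthy-like and dilated-cardiomyopathy-like presets, and the cohort
    statistics (unpaired t-tests, force-ratio vs sphericity regression).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
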