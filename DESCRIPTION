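Package: ventriflow
Title: Particle Tracking Velocimetry and Morphometry for OCT Imaging of
    Cerebrospinal Fluid Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify cerebrospinal fluid (CSF) flow and brain
    ventricle morphology from optical coherence tomography (OCT) image
    series of small transparent vertebrates such as Xenopus tadpoles.
    Implements pixel-anisotropy correction, feature-point and H-dome
    particle detection, optimal-assignment trajectory linking, windowed
    flow-velocity mapping with percentile outlier rejection, vortical
    flow-field segmentation with polarity calls, particle-density
    heatmaps, Procrustes-based cross-animal averaging of flow maps, and
    seeded region-growing volumetry of the ventricular system with
    aqueduct patency assessment. A synthetic phantom generator produces
    particle videos advected by prescribed multi-vortex flow fields and
    3D ventricle volumes with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    igraph,
    mgcv,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
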