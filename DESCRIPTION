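Package: coroflow
Title: Wall Shear Stress, Helicity and Morphometry Descriptors for
    Coronary Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for time-resolved computational
    hemodynamics of coronary arteries. Computes the canonical near-wall
    wall shear stress descriptors (TAWSS, OSI, RRT, transWSS) on
    triangulated lumen surfaces, helical-flow descriptors (local
    normalized helicity and the four bulk helicity integrals h1-h4) on
    tetrahedral lumen volumes, centerline morphometry (curvature,
    torsion, distance metric, cross-section shape index) from free-knot
    regression splines, and nonparametric species/vessel group
    comparisons (Mann-Whitney U). Includes a parametric vessel-and-flow
    synthesizer with closed-form ground truth for validation, VTK XML
    series input/output, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    splines,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'centerline-synthesis.R'
    'tube-mesh.R'
    'flow-synthesis.R'
    'cohort-synthesis.R'
    'wss-descriptors.R'
    'helicity.R'
    'morphometry.R'
    'cohort-statistics.R'
    'vtk-io.R'
    'tables-io.R'
    'pipeline.R'
    'coroflow-package.R'
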