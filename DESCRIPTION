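Package: corrmicro
Title: Correlative X-Ray Holography, Scanning SAXS and STED Image Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for correlative multimodal
    imaging of single adherent cells, combining in-line X-ray holography
    (Fresnel propagation, contrast-transfer-function inversion and iterative
    relaxed-averaged-alternating-reflections phase retrieval), scanning
    small-angle X-ray scattering (dark-field maps and principal-component
    anisotropy of diffraction patterns), and confocal/STED fluorescence
    microscopy. Includes a seeded synthetic cardiac-cell phantom generator
    for all three modalities, power-spectral-density resolution estimation
    via noise-floor cross-over analysis, a filament tracer with orientation
    statistics, and sub-pixel registration for cross-modality correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'corrmicro-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'phantom.R'
    'simulate.R'
    'holography.R'
    'saxs.R'
    'resolution.R'
    'filaments.R'
    'correlate.R'
    'io.R'
    'pipeline.R'
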