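Package: ifshear
Title: Interstitial-Fluid Flow, Shear Stress and Cardiovascular Variability
    Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline linking head-motion-induced interstitial-fluid
    flow in the brainstem to shear stress on cell surfaces and to antihypertensive
    physiological readouts. Provides 3D interstitial-space geometry extraction
    from fluorescence volumes (top-quantile cluster segmentation, moment-based
    ellipse fitting, log-normal pore-size statistics, centroidal-line
    orientation), contrast-agent spread quantification in CT-like volumes with
    flow-velocity estimation, Darcy/Kozeny-Carman permeability and fluid shear
    stress calculation over biophysical parameter ranges, beat-by-beat blood
    pressure and heart-rate variability analysis (RRI artifact rejection,
    validity rules, Hanning-windowed LF/HF band power), and rectified-integrated
    sympathetic nerve-signal processing. A seeded synthetic-data module generates
    every input with known ground truth so the full pipeline is testable without
    raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    signal,
    minpack.lm,
    jsonlite,
    RNifti,
    tiff
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Preprocessing, Visualization
RoxygenNote: 7.3.3
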