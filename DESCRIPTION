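Package: scanqc
Title: No-Reference Quality Control Metrics for Structural, Functional and
    Diffusion MRI
Version: 0.1.0
Authors@R: person("QC", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Computes no-reference quality-control metrics for structural
    MRI/CT volumes (mean slice intensity, SNR, SVNR, CNR, CVNR, TCTV,
    Forman-method FWHM smoothness, center of mass), fMRI time series
    (rigid-body motion estimation, framewise displacement, DVARS, temporal
    SNR, SFNR, outlier fractions, frequency-spectrum summaries) and
    diffusion-weighted series (per-gradient descriptors, log-linear tensor
    fits yielding FA/MD/ADC maps). Metric values are converted into
    good/bad flags against reference distributions with ROC-calibrated
    cutoffs chosen by cross-validated (sensitivity+specificity)/2 search,
    and study-level reproducibility is summarised with area-normalised
    histogram densities, Dice overlaps and metric correlation matrices.
    Ships a synthetic phantom generator (nested-ellipsoid head phantoms,
    uniform QA phantoms, 4D series with injected motion/drift/spike
    artifacts, DWI from known tensor fields) with retrievable ground truth,
    plus a command-line interface. Includes a dependency-free NIfTI-1/2
    reader and writer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
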