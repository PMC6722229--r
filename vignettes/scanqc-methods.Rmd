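---
title: "Methods: no-reference QC metrics for MRI and their automated flagging"
author: "scanqc maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: no-reference QC metrics for MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanqc)
```

## Scope and model

`scanqc` computes *no-reference* image-quality indices: quantities derived
from a single scan, without a gold-standard image, that track the artifact
load a human rater would see — noise, blur, motion, ghosting, positioning
errors. Three acquisition families are covered: 3D structural MRI/CT
volumes, 4D fMRI time series, and 4D diffusion-weighted series with a
b-value/b-vector table. On top of the per-scan metrics sits a simple
automated flagging layer: each metric is z-scored against a reference
population, compared with a per-metric cutoff range, and a scan is called
*bad* when at least three metrics are out of range.

Everything is testable without clinical data because the package ships a
phantom generator whose ground truth (masks, class means, rigid motion
parameters, diffusion tensors) is returned alongside the image.

## Structural metrics

All region statistics use the population SD convention (divisor $N$); at
image scale the difference from the sample convention is negligible, but a
fixed choice keeps hand-computed oracle values exact.

* **MSI** — the vector of per-slice mean intensities. Slice means are taken
  over all voxels of the slice (an option restricts them to head voxels);
  abrupt jumps indicate slice-level artifacts.
* **Background/head split** — the lower 10% of the pooled intensity
  distribution is background, the rest is the head. This is a deliberate,
  literal rule: when true background occupies more than 10% of the grid,
  the resulting "background SD" describes the lower tail of the noise and
  SNR-family values are inflated relative to the generative noise level.
  That is a property of the method, not a bug; reference distributions and
  cutoffs are computed under the same rule, so comparisons remain valid.
* **SNR** $= \mu_{head} / \sigma_{bg}$ (lower is worse), **SVNR**
  $= \mathrm{var}_{head}/\mathrm{var}_{bg}$ (higher is worse in the
  nominal reading), **CNR** $= |\mu_{GM}-\mu_{WM}|/\sigma_{bg}$ (lower is
  worse), **CVNR** $= |\sigma_{GM}-\sigma_{WM}|/\sigma_{bg}$, **TCTV**
  $= |\mu_{GM}-\mu_{WM}|/\sqrt{\sigma_{GM}^2+\sigma_{WM}^2}$ (lower is
  worse; the pooled SD is the quadrature sum). CVNR mirrors the CNR
  sentence structure with SDs substituted for means — the absolute
  difference is an interpretation, recorded here.
* **Brain mask** — Otsu threshold inside the head, largest 26-connected
  component, one morphological closing, cavity fill. This is intentionally
  minimal pre-processing, not a re-implementation of a skull stripper; an
  externally supplied mask bypasses it, which preserves comparability with
  pipelines that use BET or similar. On the head phantom the mask excludes
  the dark CSF shell outside the grey matter surface (there is no cavity
  to fill there), so brain-mask Dice against the CSF-inclusive truth is
  ~0.75 by construction; tissue metrics are unaffected because
  segmentation runs inside whatever mask is used.
* **Tissue classes** — one-dimensional 3-class k-means (20 restarts, fixed
  local seed) on intensities inside the brain mask, ordered by class mean
  and mapped to CSF < GM < WM for T1-like contrast; T2/FLAIR invert the
  ordering via the profile. Only class means and SDs feed the metrics, so
  posterior maps are out of scope.
* **FWHM (smoothness)** — per axis $a$, with
  $r_a = 1 - \mathrm{var}(\Delta_a I)/(2\,\mathrm{var}(I))$ over
  within-mask neighbour pairs,
  $\mathrm{FWHM}_a = v_a \sqrt{-2\ln 2 / \ln r_a}$ (the
  variance-of-derivatives estimator under a Gaussian autocorrelation
  model). White noise drives $r_a \to 0$ and the raw estimate below one
  voxel; such axes are clamped to the voxel size and flagged `"floor"`.
  *Resolvable elements* divides the brain voxel count by the geometric
  mean of the three FWHMs — the literal stated definition; the
  conventional resel count (divide by the product in voxel units) is
  available via `resel_convention = "product"`.
* **CoM** — the unweighted centroid of brain-mask voxel indices in mm.
  Both the absolute centroid and the offset from the grid centre are
  reported; auto-QC consumes the offset magnitude because it is invariant
  to acquisition matrix size, whereas the absolute centroid scales with
  the field of view (the two conventions differ by an order of magnitude
  and are not reconciled in the source material).
* **Odd–even slice difference** (phantom profile) — mean MSI over
  odd-indexed slices minus even-indexed ones, 0-based.

## fMRI metrics

* **Rigid motion** is estimated per frame against the first frame by
  maximising normalized correlation: centre-of-mass initialisation, a
  two-level multiresolution Nelder-Mead search with a tight-simplex
  restart and a quasi-Newton polish, trilinear interpolation, rotation
  centre at the volume centre. Two numerical choices matter and were fixed
  by experiment, not convention:
  1. both images are pre-smoothed with a 2-voxel-FWHM Gaussian before the
     cost — without this, interpolating a *noisy* moving frame at off-grid
     positions smooths its noise and raises the correlation, biasing the
     optimum toward spurious rotations of order 1° even at SNR 100;
  2. the cost mask is the dilated bright-object mask, which includes the
     high-contrast object edge; the lower-decile "head" region is unusable
     here because it contains most of the noise-only background.
  On noise-free phantoms the estimator recovers translations to well under
  0.1 mm for displacements up to ±5 mm and rotations to ≲0.1° for single
  rotations up to ~3°. Known limitation: for simultaneous three-axis
  rotations near 5° the correlation optimum itself sits up to ~0.3° from
  the truth (trilinear interpolation bias, verified by descent started at
  the true parameters); higher-order interpolation would remove it at a
  runtime cost pure R cannot pay.
* **FD** — Power's framewise displacement: the sum of absolute
  frame-to-frame differences of the six parameters, rotations converted to
  arc length at a 50 mm head radius; threshold 0.5 mm. The realignment
  reference is the first frame but FD differences are frame-to-frame (the
  construction of the cited algorithm); an each-frame-vs-first variant is
  a config switch.
* **DVARS** — RMS frame-to-frame signal change over the mask after
  rescaling so the median in-mask intensity of the mean volume is 1000;
  the threshold 50 then reads as a 5% signal change. No detrend is applied
  before differencing. The hand-checkable contract: a one-voxel mask with
  values (970, 1030) around a median-1000 mean volume gives DVARS exactly
  60.
* **tSNR / SFNR** — temporal mean over temporal SD; SFNR replaces the SD
  with the SD of residuals after a second-order polynomial detrend, so the
  two coincide on trend-free series.
* **Outlier fractions** — per voxel, deviations from the temporal median
  are compared with $\Phi^{-1}(1-\alpha/2)\cdot\sqrt{\pi/2}\cdot
  \mathrm{meanAD}$, $\alpha = 0.001$. The deviation scale is the *mean*
  absolute deviation: $\sqrt{\pi/2}\,\mathrm{meanAD}$ is the consistent
  Gaussian $\sigma$ estimator, which makes the rule exactly
  $\alpha$-calibrated (a median-based MAD with the same constant would
  flag ~0.5% of Gaussian samples, contradicting the rule's own stated
  calibration).
* **Velocity, spectrum, frame-wise descriptors** — volume-mean running
  difference; magnitude spectrum (DC excluded) of the mean in-mask signal
  with mean/max/peak frequency; per-frame volume mean, head-CoM change and
  FWHM; per-slice SD over time of the slice's mean intensity.

## Diffusion metrics

The gradient table is validated first (a b≈0 reference must exist,
b0 tolerance 50 s/mm²; diffusion directions must be unit vectors). MSI and
SNR reuse the structural definitions per gradient volume with the
b0-derived background; per-gradient CoM uses a per-frame head partition —
with a fixed mask the CoM could not move, and the whole point of the
vector is to reveal displaced frames. CoM displacements are reported about
their per-axis mean and therefore sum to zero.

Tensor fitting is unweighted log-linear least squares on
$\ln(S_g/S_0) = -b\,g^T D g$ (the estimator is a package choice; the
source delegates to external tooling without stating one). MD is the mean
eigenvalue, FA the usual normalised eigenvalue dispersion, and ADC the
direction-averaged $-\ln(S_g/S_0)/b$ — ADC and MD coincide for a perfect
tensor fit but are emitted separately. Voxels with non-positive signals
are excluded and flagged; negative eigenvalues are flagged, never clipped.
Collinear direction sets are rejected by the design-matrix condition
number.

## Auto-QC

z-scores use a reference mean/SD per metric and profile. Flags follow the
closed-interval rule — boundary values are *good* — and unavailable
metrics never count as bad. The scan verdict is bad when
$n_{bad} \ge 3$; the source material states both "more than 3" and "3 or
more", and the ≥ reading (the one tied to the reported best agreement) is
the default, with `strict = TRUE` for the other.

Calibration sweeps one-sided z cutoffs from −5 to 5 in steps of 0.05 in
the metric's bad direction, picks the cutoff maximising
$(\mathrm{sens}+\mathrm{spec})/2$ on the training folds of a stratified
threefold cross-validation (seeded, folds recorded), and reports held-out
sensitivity/specificity plus the trapezoidal AUC of the full-sample sweep.
Objective ties break toward the less aggressive cutoff (fewer bad calls) —
the tie rule is a documented package choice. Shipped Table-style default
cutoffs (`inst/extdata/default_cutoffs.json`) are population-specific
documentation values, never asserted by tests.

Study summaries: histogram densities are area-normalised on shared bin
grids (they integrate to 1), compared by the Dice overlap
$\sum_i \min(h_{1i}, h_{2i})\,\Delta$, and metric inter-correlations use
pairwise-complete Pearson coefficients.

## The phantom world

The default structural phantom is a 64³ voxel, 1 mm grid with nested
ellipsoid compartments — scalp/skull 45, CSF 30, GM 70, WM 110 intensity
units — and Rician noise σ = 5, a realistic 3T regime. The geometry is
deliberately anisotropic (head semi-axes 0.70/0.84/0.80 of the half-extent,
inner compartments off-centre): a rotationally symmetric phantom leaves
in-plane rotation unobservable and would make motion recovery vacuous.
Artifact injections mimic the standard taxonomy: tripled noise, Gaussian
blur, an attenuated N/2 ghost replica along the phase axis, quadratic bias
fields, rigid motion events (persistent — the head moves and stays),
polynomial drift, and frame spikes.

Two rendering paths exist on purpose. 3D structural phantoms are hard
piecewise-constant (class statistics are exact, segmentation oracles are
trivial). 4D frames are rendered analytically with a one-voxel soft
partial-volume edge and a deterministic intensity texture defined in
object coordinates, both of which move rigidly and exactly with the head:
resampling a base image instead would stamp interpolation error into the
"ground truth" and displace the registration optimum by ~0.5°, and an
untextured blob leaves rotation ill-conditioned. A green motion test
therefore establishes parameter recovery on band-limited, textured,
noise-free data — not performance on clinical EPI with distortion,
spin-history effects or through-plane dropout, none of which the generator
emulates. Likewise the quantile background rule, k-means segmentation and
Otsu brain mask are exercised on geometry far cleaner than real anatomy;
green tests establish the *arithmetic* of each metric and the documented
contracts, not clinical validity.

`make_reference_population()` samples mild between-scan variation (noise
σ ~ U(3,6), ±10% intensity gain, ~2 mm positioning jitter) and injects
heavy compound artifacts into a deterministic `round(n × prevalence)`
subset. On this world the calibrated ≥3-bad-metrics rule separates good
from bad scans essentially perfectly; note that two metrics (SVNR, FWHM)
move *against* their nominal bad direction under the compound artifact —
tripled noise lowers measured smoothness faster than blur raises it — a
useful reminder that univariate directionality is population-dependent.

## Numerical choices and degenerate inputs

* Quantiles are linear-interpolation sample quantiles (type 7) for
  cross-platform determinism.
* Constant images, empty masks, single-class label sets, zero background
  SD, and all-metrics-unavailable decisions raise errors or explicit
  flags (`"undefined"`, `"unavailable"`, `"undetermined"`); nothing
  propagates silent `Inf`s into the flagging layer.
* FWHM estimates at 64³ carry ~3% per-axis sampling SD at 9 mm kernels;
  the estimator's 5%-accuracy contract is asserted on the mean of a few
  independent realisations.
* All randomness (k-means restarts, fold assignment, phantom noise) runs
  under locally scoped seeds that restore the caller's RNG state.
* The NIfTI-1/2 reader and NIfTI-1 writer are built in (no R NIfTI package
  is assumed); the reader is cross-checked in the test suite against an
  independent Python implementation.

## Known limitations

Beyond the registration bias at extreme rotations noted above: DICOM is
not read (convert to NIfTI first); eddy-current and bias-field corrections
are not performed (inputs are taken as given); DTI has no scalar auto-QC
flags (its metrics are vectors); tractography, viewers and report
rendering are out of scope.
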