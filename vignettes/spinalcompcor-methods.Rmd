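---
title: "Data-driven nuisance regression for spinal cord fMRI: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven nuisance regression for spinal cord fMRI: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Spinal cord BOLD fMRI is dominated by structured, non-neural signal:
cardiac-driven pulsation of cerebrospinal fluid (CSF) and blood vessels,
respiration-driven B0 shifts from the lungs, slow scanner drift, and bulk
motion. At a typical TR of 2 s the ~1 Hz cardiac fluctuation aliases into
the frequency band of interest and cannot be removed by temporal filtering.
Recording-based corrections (RETROICOR-style Fourier regressors of cardiac
and respiratory phase) help, but require good physiological recordings that
are not always available.

This package implements a CompCor-style, data-driven alternative tailored
to the cord: nuisance regressors are the leading principal components of
the voxel timeseries in a *noise region of interest* drawn outside the
spinal cord and CSF — tissue whose fluctuations share the physiological
and instrumental noise sources of the cord but carry no neural signal —
with the number of retained components chosen per run by a parallel
analysis against surrogate data.

## The procedure

For each fMRI run, slice by slice (axial slices are the third voxel axis
throughout):

1. **Noise ROI** (`build_noise_roi()`): the manually drawn cord + CSF mask
   is dilated in-plane by 18 mm (rounded to whole voxels per axis), the
   cord/CSF mask is subtracted, and a 3-voxel border at the in-plane
   field-of-view edge is removed. The 18 mm default reaches the edge of a
   typical reduced-FOV cervical acquisition; both values are configurable
   (`noise_roi_spec()`).
2. **Slice-wise PCA** (`extract_slice_matrix()`, `slice_pca()`): all noise
   ROI voxel timeseries on a slice form a T × V matrix (rows timepoints,
   columns voxels). Columns are mean-centered — not variance-scaled — and
   decomposed by SVD, giving N = min(T − 1, V) components with eigenvalues
   λ_i = s_i²/(T − 1) (the sample-covariance eigenvalues).
3. **IAAFT surrogates** (`iaaft_surrogate()`, `build_surrogate_set()`):
   for every voxel, 50 surrogate timeseries are generated by the iterative
   amplitude adjusted Fourier transform: starting from a random permutation
   of the template, each iteration replaces the Fourier amplitudes with the
   template's (keeping current phases) and then rank-order remaps the values
   onto the template's sorted values. Surrogates preserve each voxel's
   amplitude distribution exactly and its power spectrum approximately,
   with randomized phases — a "chance" version of the data with the same
   temporal autocorrelation.
4. **Parallel analysis** (`run_parallel_analysis()`): 500 surrogate slice
   matrices are assembled by drawing one surrogate per voxel; PCA is run
   on the template and on each surrogate matrix. The per-slice cutoff is
   where the template eigenvalue curve stops exceeding the mean surrogate
   curve — the last component explaining more variance than chance. The
   run-level component count is the median cutoff across slices (rounded
   half-up).
5. **Model assembly** (`assemble_design()`): three nested subject-level
   designs —
   * *Base*: task + X/Y motion + CSF regressor + 16 RETROICOR columns
     (19 nuisance regressors with 2 motion columns);
   * *Extended*: Base + the k retained PCA regressors;
   * *SpinalCompCor*: task + motion + CSF + PCA only (no recording-based
     regressors; 3 + k nuisance regressors).
   The CSF regressor is the mean timeseries of the top-20%-variance CSF
   voxels per slice; RETROICOR phases are evaluated at each slice's
   acquisition time so all physiological columns are genuinely slice-wise.
6. **GLM and F-tests** (`fit_glm()`, `nested_f_test()`,
   `omnibus_f_test()`): voxel-wise least squares within the cord mask after
   projecting a discrete-cosine high-pass basis (cutoff 100 s) out of both
   the data and the regressors. The Extended-vs-Base nested F-test asks
   whether the PCA regressors explain additional cord variance; omnibus
   F-tests on the RETROICOR group (Base) and the PCA group (SpinalCompCor)
   are compared by spatial Spearman correlation of their z-transformed F
   maps to ask whether data-driven regressors capture the same variance as
   recording-based ones.
7. **Evaluation** (`tsnr()`, `dice()`, `activation_change()`,
   `seed_connectivity()`): residual tSNR (functional mean added back;
   mean/SD with the n − 1 denominator), Dice overlap and
   activation-change counts between significance masks, and slice-wise
   seed connectivity between the four gray-matter horns (mean ROI
   timeseries, full Pearson correlation, Fisher r-to-z, averaged across
   slices by pair class V–V, D–D, V–D within and between hemicords).

`run_pipeline()` orchestrates all stages from one configuration (R list or
YAML) with every random draw derived from a single seed through named
substreams, so a run is reproducible byte-for-byte. When the component
count is `"auto"` and the parallel analysis was run on a truncated series
(to compare runs of different lengths fairly), the count used for modeling
is re-estimated on the full series, since longer runs legitimately support
more components.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `dilation_mm` | 18 | mm | in-plane reach of the noise ROI |
| `edge_trim_voxels` | 3 | voxels | FOV border removed from the ROI |
| `n_per_voxel` | 50 | — | surrogates per voxel |
| `n_matrices` | 500 | — | surrogate matrices per slice |
| `max_iter` | 500 | — | IAAFT iteration cap |
| `truncate_to` | none | volumes | common length for cross-run comparison |
| `top_fraction` | 0.2 | — | CSF voxels averaged (top temporal variance) |
| `order` | 4 | — | RETROICOR Fourier order (4M = 16 columns) |
| `hp_cutoff_s` | 100 | s | discrete-cosine high-pass cutoff |
| `alpha` | 0.05 | — | significance level (uncorrected) |

## Numerical and design choices

Several details are not fixed by the method's description and were decided
once, as follows:

* **Dilation is strictly 2-D (in-plane).** The pipeline is slice-wise
  throughout and axial slices are thick (3–5 mm) relative to the in-plane
  resolution, so cross-slice dilation would mix anatomy. The mm radius is
  rounded to whole voxels per in-plane axis independently, giving an
  elliptical footprint under anisotropic voxels
  (squared-voxel-normalized distance ≤ 1).
* **Edge trim** removes a fixed border of `edge_trim_voxels` on both
  in-plane axes.
* **Mask thresholding** uses strict inequality (> 0.5): deterministic at
  the boundary.
* **PCA scaling.** Columns are mean-centered but not variance-scaled,
  matching the covariance (not correlation) convention of the standard PCA
  implementations this mirrors. Component signs are fixed by making each
  component's largest-magnitude loading positive, so results are
  deterministic across platforms. Zero-variance voxels are dropped, not
  jittered.
* **PC regressors** are the score timeseries normalized to unit sample
  variance. Normalization only conditions the design matrix; fitted models
  are unchanged.
* **IAAFT convergence** stops when the rank ordering of the surrogate is
  unchanged between consecutive iterations (the standard stopping rule; a
  genuine fixed point, since an unchanged ordering reproduces the same
  surrogate). The final step is always the amplitude adjustment, so the
  output's value multiset equals the template's exactly. Ties in the
  rank-order remap are broken by stable ordering. The zero-frequency
  Fourier term is copied from the template. Per-surrogate RNG substreams
  are derived by hashing (base seed, slice, voxel, replicate), so results
  do not depend on execution order.
* **Spectrum preservation** is quantified by
  `surrogate_spectrum_error()`: the RMS (2-norm) relative error of the
  non-DC half-spectrum amplitudes. A single IAAFT surrogate at T = 160 has
  an intrinsic error floor near 2–3% at its fixed point (we verified the
  same floor in an independently coded reference implementation); the mean
  amplitude spectrum of a 50-surrogate set — the quantity the parallel
  analysis consumes through mean eigenvalue curves — agrees with the
  template to well under 2%.
* **Scree intersection** is operationalized as a prefix rule: the cutoff
  is the count of leading components whose template eigenvalue strictly
  exceeds the mean surrogate eigenvalue, stopping at the first violation;
  re-crossings further down the curve are ignored, and no interpolation
  between integer component indices is attempted. Surrogate matrix
  sampling draws with replacement, independently per voxel and matrix.
* **Median across slices** of integer cutoffs can be half-integral; it is
  rounded half-up.
* **Peak detection** (unspecified upstream) is local maxima above a
  rolling median with a refractory period (cardiac 0.4 s, respiratory
  1.5 s defaults). The respiratory phase uses the conventional
  amplitude-histogram equalization signed by the belt derivative.
* **GLM.** Ordinary least squares is the default; the established
  subject-level tools perform locally regularized autocorrelation
  prewhitening, which this package does not replicate. A per-voxel lag-1
  autoregressive whitening option (`prewhiten = "ar1"`) is provided and
  documented as approximate. The residual degrees of freedom subtract both
  the design rank and the discrete-cosine filter basis size, because the
  filter is a projection applied to data and regressors alike (the two
  formulations — filtering both sides, or adding the basis as regressors —
  give identical fits, and the tests assert this). F-to-z maps use the
  upper-tail survival function evaluated in log space, so z stays finite
  for very large F.
* **Connectivity.** Fisher's transform clips |r| at 1 − 1e−7; residual
  standard deviations use the n − 1 denominator; slices missing any horn
  ROI are excluded from averages rather than zero-filled.

## The synthetic phantom

`simulate_phantom()` builds a ground-truth-known test bed: concentric
cord (radius 4 mm) and CSF (outer radius 6 mm) discs inside a tissue
slab on a 32 × 32 × 6 grid of 1 × 1 × 3 mm voxels, 160 volumes at TR 2 s
by default. Signal components, each individually switchable:

* *planted components*: K orthogonal, unit-variance, mildly smoothed
  timecourses on random supports inside the noise region — the
  PCA-recoverable structure whose count the parallel analysis should
  recover;
* *cardiac*: a pulsatile low-order Fourier waveform of the true cardiac
  phase (jittered ~1 Hz beats), sampled at each slice's acquisition time
  and concentrated in CSF and two vessel columns — deliberately aliased at
  TR 2 s, and exactly removable by order-4 RETROICOR so recording-based
  correction is separately testable;
* *respiratory* (~0.25 Hz, muscle support), *quadratic drift* (global),
  optional *edge-weighted motion spikes*, optional *block task* confined
  to the ventral horns, optional shared horn timecourses planting a known
  seed-connectivity level, and white thermal noise.

`simulate_physio()` generates matching pulse and respiratory-belt traces;
with a shared seed its beat times equal the phantom's injected cardiac
event times, so peak detection and phase estimation can be validated
against truth. The phantom records per-voxel noise-free variance, so
variance bookkeeping is testable.

What the phantom does *not* emulate: MR physics (EPI distortion, B0
inhomogeneity, coil profiles), realistic motion (only global spikes),
spatially correlated thermal noise, and serially correlated noise floors.
Tests passing on the phantom therefore validate the algorithmic pipeline
and its calibration, not robustness to every property of in vivo data.

## Validation conditions and problem sizes

The package validates itself on phantom regimes chosen once:

* *Component recovery*: single-slice phantoms with K = 5 planted
  components at ≥ 10× thermal variance in a ~290-voxel noise region
  (26 × 26 grid), T = 160, with the surrogate budget scaled to 20 per
  voxel and 100 matrices; the median cutoff must equal 5 ± 1 in ≥ 90% of
  20 seeds. Pure-noise phantoms under the same budget must give a median
  cutoff ≤ 2 across 20 seeds (surrogates preserve each voxel's spectrum,
  so template and surrogate eigencurves coincide in expectation).
* *GLM calibration*: 10,000 white-noise voxels; the nested-test p < 0.05
  rate must fall in the exact binomial 99% interval around 0.05.
* *RETROICOR efficacy*: injected order-4 cardiac contamination generated
  from simulated beat times must lose ≥ 99% of its variance under the
  Base model.
* *Connectivity*: a planted ventral–ventral correlation of 0.6 (T = 434)
  must be recovered within ±0.1 in slice-averaged Fisher z.
* *Determinism*: the full pipeline run twice under one seed must produce
  byte-identical outputs.

These checks run in a few minutes on a single CPU; `scripts/acceptance.R`
recomputes all of them from scratch for any seed.

## Known limitations

* No prewhitening beyond the optional AR(1) approximation; inference on
  strongly autocorrelated in vivo data will be optimistic, as it is for
  any OLS fit.
* The parallel analysis is univariate per voxel: surrogates preserve each
  voxel's spectrum but not cross-voxel correlation, which is precisely
  what makes the retained components identifiable, but also means the
  null model ignores spatially correlated thermal noise.
* Motion correction, template registration and group-level permutation
  inference are out of scope; inputs are assumed motion-corrected and
  masks are assumed to be in the functional grid.
* Physiological sampling rate is not stored in TSV exchange files and
  must be supplied by the caller.
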