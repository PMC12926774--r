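# spinalcompcor

Data-driven denoising for spinal cord fMRI.

Spinal cord BOLD timeseries are dominated by structured physiological
noise — cardiac pulsation of the cerebrospinal fluid (CSF) and vessels,
respiration-driven field shifts, drift and motion — and at TR = 2 s the
~1 Hz cardiac signal aliases into the band of interest. This package
derives nuisance regressors from the data themselves, for the common case
where physiological recordings are missing or poor:

1. build a **noise ROI** outside the cord and CSF by in-plane dilation of
   the cord/CSF mask (default 18 mm), subtraction, and field-of-view edge
   trimming;
2. run **slice-wise PCA** (by SVD) on the T × V matrix of noise-ROI voxel
   timeseries;
3. decide how many components to keep by **parallel analysis**: compare
   the template eigenvalue curve against the mean curve of 500 surrogate
   matrices assembled from **IAAFT surrogates** (50 per voxel) that
   preserve each voxel's amplitude distribution and power spectrum with
   randomized phases. The per-slice cutoff is where the template scree
   stops exceeding the surrogate scree — the last component explaining
   more variance than chance — and the run-level count k is the median
   across slices.

The retained components enter subject-level GLMs alongside standard
regressors. Three nested designs are supported, written here as
`Y ~ task + nuisance`:

| model | nuisance regressors |
|---|---|
| Base | motion (X, Y) + CSF + RETROICOR (8 cardiac + 8 respiratory) — 19 columns |
| Extended | Base + k PCA components |
| SpinalCompCor | motion + CSF + k PCA components (no recordings needed) |

The package also provides the full evaluation stack: discrete-cosine
high-pass filtering (100 s) applied identically to data and regressors,
voxel-wise OLS within the cord mask, nested and omnibus F-tests with
log-space z maps, residual tSNR, spatial Spearman agreement of F maps,
Dice overlap and activation-change counts, slice-wise seed connectivity
between gray-matter horns (Fisher r-to-z), and a synthetic cord phantom
with known ground truth that makes every stage testable without real
data. See the vignette in `vignettes/spinalcompcor-methods.Rmd` for the
model details and design decisions.

## Worked example

Simulate a phantom with 4 planted noise components plus cardiac,
respiratory and drift noise, then let the parallel analysis decide how
many PCA regressors to keep:

```r
library(spinalcompcor)

cfg <- phantom_config(n_slices = 3, k_components = 4, seed = 42)
phantom <- simulate_phantom(cfg)

roi <- build_noise_roi(phantom$masks$cord_csf,
                       noise_roi_spec(dilation_mm = 18, edge_trim_voxels = 3))
roi
#> <mask_volume> 32 x 32 x 3 voxels, 1692 set

pa <- run_parallel_analysis(phantom$func, roi, n_per_voxel = 20,
                            n_matrices = 100, base_seed = 7)
pa
#> <parallel_analysis_result> 3 slices; per-slice cutoffs: 4, 4, 4
#>   median cutoff: 4

pa_summary(pa)
#> # A tibble: 3 × 4
#>   slice cutoff n_components n_matrices
#>   <int>  <int>        <int>      <int>
#> 1     1      4          159        100
#> 2     2      4          159        100
#> 3     3      4          159        100
```

Each slice offers N = min(T − 1, V) = 159 components; the scree
intersection retains 4 per slice — exactly the number planted — and the
run-level median is 4. The retained components become unit-variance
nuisance regressors:

```r
m <- extract_slice_matrix(phantom$func, roi, 1)
m
#> <slice_matrix> slice 1: 160 timepoints x 564 voxels

pcs <- pc_regressors(slice_pca(m), pa$median_cutoff)
names(pcs)
#> [1] "PC1" "PC2" "PC3" "PC4"
```

`autoplot(pa$per_slice[[1]])` draws the scree plot with the cutoff.
`assemble_design()`, `fit_glm()`, `nested_f_test()` and `tsnr()` take it
from there; `run_pipeline()` runs everything (ROI → PCA → parallel
analysis → designs → GLMs → evaluation) from one seeded YAML/list
configuration and writes NIfTI maps, TSV tables and a JSON manifest.

A thin command-line wrapper is installed as `exec/spinalcompcor`:

```sh
spinalcompcor simulate --out phantom/ --seed 1 --k 5
spinalcompcor noise-roi --mask phantom/cord_csf.nii --out roi.nii
spinalcompcor parallel-analysis --func phantom/func.nii --roi roi.nii \
    --n-per-voxel 50 --n-matrices 500 --seed 1 --out pa.json
spinalcompcor run --config run.yaml
```

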