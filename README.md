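# estatics

Joint multi-contrast R2\* mapping with robust fitting, for quantitative
MRI pipelines built on multi-echo FLASH acquisitions.

## The problem

Multi-parameter mapping protocols acquire three multi-echo gradient-echo
scans with different basic contrasts — proton-density- (PDw), T1- (T1w)
and magnetization-transfer-weighted (MTw). The apparent transverse
relaxation rate R2\* is conventionally fitted from the PDw echoes alone,
which makes the map hostage to motion during that one acquisition: a few
phase-encode lines acquired during head motion turn into ringing across
the whole R2\* map.

This package estimates a **single R2\* jointly from all contrasts**. Each
contrast $k$ keeps its own intercept while sharing the decay rate:

$$\varepsilon = \sum_{k=1}^{k_{\max}} \sum_{n=1}^{n_{\max}(k)}
 \left[\ln I_k(TE_n) + \hat R_2^*\, TE_n - \ln \hat I_k(0)\right]^2$$

minimized per voxel either by ordinary least squares (`fit_ols()`) or by
iteratively reweighted robust fitting (`fit_robust()`) that detects and
rejects motion-corrupted echoes. Two robust variants are provided:
voxel-wise weighting with a wide confidence interval (higher SNR) and a
factorized voxel × line × plane weighting with a tight interval (more
robust), matching the line/plane structure of Cartesian motion artifacts.

A synthetic phantom (`make_phantom()`, `simulate_cohort()`) with Rician
noise and k-space motion-artifact injection (`corrupt_kspace()`) makes
every claim testable without scanner data, and `compare_methods()` /
`roi_stats()` implement the standard coefficient-of-variation evaluation.

## Worked example

```r
library(estatics)

# a 64^3 three-contrast phantom (6/6/8 echoes, shared R2*, Rician SNR 50),
# with 15% of phase-encode lines of the three longest PDw echoes corrupted
ph <- make_phantom(phantom_spec(seed = 42))
ph$dataset$contrasts$PDw <- corrupt_kspace(ph$dataset$contrasts$PDw,
                                           corruption_spec(seed = 42))

fit_pdw <- fit_ols(ph$dataset, subset = "PDw")   # conventional estimator
fit_rob <- fit_robust(ph$dataset)                # factorized robust joint fit

roi <- erode_mask(ph$truth$labels == 1L, 2)      # homogeneous WM-like core
roi_stats(fit_pdw$r2s, roi)
#> <roi_stats> n=10686 mean=19.99 sd=6.458 cov=0.3231
roi_stats(fit_rob$r2s, roi)
#> <roi_stats> n=10686 mean=20.91 sd=2.08 cov=0.09946
cov_reduction(0.09946, 0.3231)
#> [1] 69.21696
```

The corrupted single-contrast map carries a 32% coefficient of variation
in a region whose true R2\* is a constant 21 s⁻¹ (ground truth is
returned alongside every simulation); the robust joint fit brings it down
to 10% — a 69% CoV reduction — and pulls the ROI mean back toward truth.

For file-based workflows, `read_contrast()` / `write_fit_result()` handle
NIfTI-1 volumes with JSON echo-time sidecars (`{"EchoTime_ms": [...]}`),
and a thin command-line wrapper ships in `inst/cli/estatics.R`:

```sh
Rscript inst/cli/estatics.R simulate --n 10 --seed 7 --out cohort/
Rscript inst/cli/estatics.R fit --method robust --out maps/ \
    pdw.nii.gz,pdw.json t1w.nii.gz,t1w.json mtw.nii.gz,mtw.json
Rscript inst/cli/estatics.R evaluate --cohort cohort/ --out results.csv
```

See `vignettes/estatics-methods.Rmd` for the model, the robust-fitting
design choices, and what the synthetic validation does and does not show.

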