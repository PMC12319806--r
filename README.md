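# tractgr

Tract-specific aggregate g-ratio mapping from multi-modal MRI.

## The problem

The g-ratio of a myelinated axon — inner (axon) over outer
(axon + myelin) diameter — modulates conduction velocity. Its
area-weighted voxel analogue can be mapped in vivo by combining a
myelin marker (MTsat) with multi-shell diffusion MRI, and projected onto
tractography streamlines to characterize white matter tracts. The
standard approach, **tractometry** (sample the voxel-wise g-ratio map
along each streamline, take the per-streamline median and the per-edge
mean), is biased wherever fiber bundles cross: most white matter voxels
contain several fiber populations, and every one of them contaminates
the sampled value.

`tractgr` implements the **tract-specific** alternative. Each voxel's
signal is modeled as a non-negative linear combination of
per-streamline contributions (microstructure-informed tractography, in
the COMMIT mold), which separates crossing tracts at the fit level:

1. filter the tractogram and map tract ICVF by fitting a
   stick–zeppelin–ball dictionary to the multi-shell signal
   (`fit_filtering()`), with D∥ = 1.7e-3, D⊥ = 0.51e-3,
   D_iso = {1.7e-3, 3.0e-3} mm²/s;
2. calibrate MTsat to a myelin volume fraction, MVF = α_calib · MTsat,
   by inverting AVF = (1−MVF)(1−ISOVF)·ICVF and
   g = √(AVF/(AVF+MVF)) at the reference g = 0.7 in a high-FA region
   (`compute_alpha_calib()`);
3. fit per-streamline myelin cross-sectional areas to the MVF map
   (`fit_myelin()`), and — after scaling the diffusion signal by
   (1−MVF), since myelin is diffusion-invisible — per-streamline *true*
   intra-axonal areas (`fit_true_axonal()`);
4. sum myelin volume (MV) and intra-axonal volume (AV) per connectome
   edge and compute the edge g-ratio g = √(AV/(AV+MV))
   (`build_connectome()`), since g itself is not additive;
5. filter edges by tract caliber (bottom 80% removed across the
   cohort) and by 50% consensus across subjects (`caliber_filter()`,
   `consensus_filter()`), and compare scan–rescan repeatability and
   variability (`icc_scan_rescan()`, `bland_altman()`, `cova()`,
   `fit_mixed_model()`).

No external data are needed: `build_phantom()` generates synthetic
crossing-fiber datasets (streamlines, multi-shell DWI, MT-related maps,
parcellation) with exact per-bundle axon/myelin ground truth, and the
whole pipeline is validated against it.

## Worked example

```r
library(tractgr)

# two bundles (g = 0.60 / 0.80) crossing at ~20 deg in a 16^3 mm grid,
# 50 streamlines each plus 10 implausible arcs
ph  <- build_phantom(phantom_spec(seed = 1))
res <- run_phantom_pipeline(ph)   # simulate DWI, 3 NNLS solves, connectome

res$alpha_calib
#> [1] 20                          # phantom's true MTsat-to-MVF factor

length(res$kept)                  # streamlines surviving the filter
#> [1] 77                          # all 10 implausible arcs removed

compare_edge_g(res, ph$truth)
#>   bundle g_true g_tract_specific g_tractometry bias_tract_specific bias_tractometry
#> 1      1    0.6        0.6003788     0.6393196         0.000378829       0.03931964
#> 2      2    0.8        0.8010098     0.7674055         0.001009801      -0.03259450
```

Reading the table: the tract-specific edge g-ratios land within 0.001
of the true bundle values, while tractometry on the same filtered
streamlines is pulled toward the crossing bundle by 0.03–0.04 in both
directions — the partial-volume bias the method removes, and the
contrast broadening seen when the two techniques are compared at the
connectome level.

A thin command-line front end covers the file-based workflow
(NIfTI / TCK / FSL bvals–bvecs):

```sh
Rscript inst/cli/tractgr phantom --out phantom_dir --seed 1
Rscript inst/cli/tractgr fit --dwi phantom_dir/dwi.nii --bvals phantom_dir/dwi.bval \
    --bvecs phantom_dir/dwi.bvec --tck phantom_dir/tractogram.tck \
    --mask phantom_dir/mvf.nii --mvf phantom_dir/mvf.nii --stage myelin --out fit
Rscript inst/cli/tractgr gratio --mvf phantom_dir/mvf.nii \
    --icvf phantom_dir/icvf.nii --isovf phantom_dir/isovf.nii --out g.nii
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch, the calibration-closure quantity: it builds a
synthetic phantom with a homogeneous high-FA calibration region,
derives the global calibration factor by inverting the g-ratio model at
the 0.7 reference on FA > 0.8 voxels, applies the MVF calibration and
the AVF/g-ratio equations, and reports the ROI mean g-ratio as JSON.

## Documentation

`vignettes/tract-gratio-methods.Rmd` describes the forward model, the
phantom's design (what it emulates and what it deliberately does not),
every numerical choice (solver, thresholds, tie rules, interpolation),
and known limitations.
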