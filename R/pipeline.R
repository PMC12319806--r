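# End-to-end phantom pipelines: calibration, tract-specific g-ratio
# mapping, and the tractometry comparator, wired together the way the
# in-vivo pipeline runs (filter -> calibrate -> myelin fit -> myelin-
# corrected axonal fit -> connectome; tractometry on the same filtered
# tractogram).

#' A homogeneous single-bundle calibration phantom
#'
#' Dense, coherent bundle (about 80% fiber volume, FA > 0.8) with
#' g-ratio equal to the calibration reference, low free water - a stand-in
#' for the splenium calibration region.
#'
#' @param g_ref bundle g-ratio (default 0.7)
#' @param seed RNG seed
#' @param noise_sigma DWI noise sd
#' @return a `phantom`
#' @export
calibration_phantom <- function(g_ref = 0.7, seed = 1, noise_sigma = 0) {
  build_phantom(phantom_spec(
    bundles = single_bundle(g = g_ref),
    n_spurious = 0, isovf_background = 0.01,
    jitter_sd = 0.2, noise_sigma = noise_sigma, seed = seed))
}

#' Calibrate the MTsat-to-MVF factor on a phantom
#'
#' Runs [compute_alpha_calib()] on the phantom's MTsat/ICVF/ISOVF/FA
#' grids and its single-fiber high-FA calibration ROI.
#'
#' @param phantom a `phantom`
#' @param g_ref reference g-ratio
#' @param fa_thresh FA selection threshold
#' @return a `calibration_result`
#' @export
calibrate_on_phantom <- function(phantom, g_ref = 0.7, fa_thresh = 0.8) {
  t <- phantom$truth
  compute_alpha_calib(t$mtsat, t$icvf, t$isovf, t$fa, phantom$roi_mask,
                      g_ref = g_ref, fa_thresh = fa_thresh)
}

#' Run the tract-specific and tractometry pipelines on a phantom
#'
#' Simulates the multi-shell DWI, filters the tractogram (first NNLS
#' solve), derives the MVF map from the phantom MTsat via the supplied
#' calibration factor, fits per-streamline myelin CSA (second solve) and
#' - after myelin correction of the diffusion signal - true intra-axonal
#' CSA (third solve), aggregates MV/AV into a connectome with edge
#' g-ratios, and runs tractometry on the volumetric g-ratio map using the
#' same filtered tractogram.
#'
#' @param phantom a `phantom` (from [build_phantom()])
#' @param alpha_calib MTsat-to-MVF calibration factor; default is
#'   calibrated on a matching homogeneous calibration phantom
#' @param scheme an [acquisition_scheme()]
#' @param kernels a [kernel_params()]
#' @param noise_seed seed for the DWI noise draw
#' @param max_iter NNLS iteration budget for the three solves. The
#'   noiseless phantom systems have long flat valleys (redundant
#'   near-parallel streamlines), so the pipeline requests a deeper budget
#'   than the solver's general-purpose default
#' @param ... passed to [solve_nnls()]
#' @return list: `connectome`, `tractometry` (edge table), `filtering`
#'   (filter result incl. tract ICVF), `axonal`, `myelin` (weight
#'   tables), `g_map`, `mvf_map`, `edges`, `medians`, `alpha_calib`,
#'   `dwi`
#' @export
run_phantom_pipeline <- function(phantom, alpha_calib = NULL,
                                 scheme = default_scheme(),
                                 kernels = kernel_params(),
                                 noise_seed = phantom$spec$seed + 1000L,
                                 max_iter = 50000, ...) {
  truth <- phantom$truth
  gs <- dim(truth$mvf)
  affine <- phantom$affine
  if (is.null(alpha_calib)) {
    calib <- calibrate_on_phantom(calibration_phantom(seed = phantom$spec$seed))
    alpha_calib <- calib$alpha_calib
  }
  dwi <- simulate_dwi(truth, phantom$streamlines, scheme, kernels,
                      noise_sigma = phantom$spec$noise_sigma,
                      seed = noise_seed, segmap = phantom$segmap)
  mask <- streamline_mask(phantom$segmap, gs)

  filt <- fit_filtering(dwi, phantom$streamlines, scheme, kernels, mask,
                        affine, segmap = phantom$segmap,
                        max_iter = max_iter, ...)
  kept <- which(filt$keep)
  streamlines_f <- phantom$streamlines[kept]
  segmap_f <- structure(phantom$segmap[kept], class = "segment_map")
  mask_f <- streamline_mask(segmap_f, gs)

  mvf_map <- pmin(pmax(alpha_calib * truth$mtsat, 0), 1 - 1e-6)
  my <- fit_myelin(mvf_map, streamlines_f, mask_f, affine,
                   segmap = segmap_f, max_iter = max_iter, ...)
  corrected <- myelin_correct_signal(dwi, mvf_map, scheme, mask = mask_f)
  ax <- fit_true_axonal(corrected, streamlines_f, scheme, kernels, mask_f,
                        affine, segmap = segmap_f, max_iter = max_iter, ...)

  edges <- assign_edges(streamlines_f, phantom$parcellation, affine)
  nv <- node_volumes(phantom$parcellation, affine)
  conn <- build_connectome(edges, ax$weights, my$weights, nv)

  avf_map <- compute_avf(mvf_map, truth$isovf, truth$icvf)
  g_map <- compute_gratio(avf_map, mvf_map)
  meds <- tractometry_medians(g_map, streamlines_f, affine)
  tm <- edge_tractometry(meds, edges)

  list(connectome = conn, tractometry = tm, filtering = filt,
       axonal = ax$weights, myelin = my$weights,
       axonal_fit = ax$fit, myelin_fit = my$fit, g_map = g_map,
       mvf_map = mvf_map, edges = edges, medians = meds,
       alpha_calib = alpha_calib, dwi = dwi, kept = kept)
}

#' Match pipeline edge estimates to phantom bundle ground truth
#'
#' @param result a [run_phantom_pipeline()] result
#' @param truth the phantom's `phantom_truth`
#' @return data frame per bundle: true and estimated tract-specific and
#'   tractometry edge g-ratios and their signed biases
#' @export
compare_edge_g <- function(result, truth) {
  te <- truth$edges
  out <- lapply(seq_len(nrow(te)), function(i) {
    sel <- result$connectome$node_a == te$node_a[i] &
      result$connectome$node_b == te$node_b[i]
    sel_t <- result$tractometry$node_a == te$node_a[i] &
      result$tractometry$node_b == te$node_b[i]
    g_ts <- if (any(sel)) result$connectome$g[sel] else NaN
    g_tm <- if (any(sel_t)) result$tractometry$g[sel_t] else NaN
    data.frame(bundle = te$bundle[i], g_true = te$g[i],
               g_tract_specific = g_ts, g_tractometry = g_tm,
               bias_tract_specific = g_ts - te$g[i],
               bias_tractometry = g_tm - te$g[i])
  })
  do.call(rbind, out)
}
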