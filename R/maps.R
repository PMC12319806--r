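# Quantitative map computation: MTsat from the MT-weighted GRE signal,
# g-ratio calibration against a reference region, AVF and g-ratio maps,
# and a log-linear tensor FA fit.

#' Magnetization transfer saturation from an MT-weighted GRE
#'
#' Per voxel: `MTsat = (S0 a B1 / S_MTw - 1) TR / T1 - (a B1)^2 / 2`.
#' Voxels with non-positive MT-weighted signal yield NaN (counted in a
#' message).
#'
#' @param s_mtw MT-weighted signal grid
#' @param s0 equilibrium signal grid
#' @param t1 longitudinal relaxation time grid (ms)
#' @param flip_angle excitation flip angle of the MT-weighted image (rad)
#' @param b1 relative transmit field (dimensionless, default 1)
#' @param tr repetition time of the MT-weighted sequence (ms)
#' @return MTsat grid (dimensionless fraction)
#' @export
compute_mtsat <- function(s_mtw, s0, t1, flip_angle = 6 * pi / 180, b1 = 1,
                          tr = 27) {
  a <- flip_angle * b1
  out <- (s0 * a / s_mtw - 1) * tr / t1 - a^2 / 2
  bad <- !(s_mtw > 0)
  if (any(bad, na.rm = TRUE)) {
    message(sum(bad, na.rm = TRUE),
            " voxel(s) with non-positive MT-weighted signal set to NaN")
    out[bad] <- NaN
  }
  out
}

#' Intra-axonal volume fraction
#'
#' `AVF = (1 - MVF) (1 - ISOVF) ICVF`, elementwise.
#'
#' @param mvf,isovf,icvf grids in `[0, 1]`
#' @return AVF grid
#' @export
compute_avf <- function(mvf, isovf, icvf) {
  (1 - mvf) * (1 - isovf) * icvf
}

#' Aggregate g-ratio from axon and myelin volume (fractions)
#'
#' `g = sqrt(AVF / (AVF + MVF))`; NaN where both are zero. Works equally
#' at the voxel level (volume fractions) and at the edge level (volumes).
#'
#' @param avf intra-axonal volume (fraction) grid or vector
#' @param mvf myelin volume (fraction) grid or vector
#' @return g-ratio values in `[0, 1]`, NaN where undefined
#' @export
compute_gratio <- function(avf, mvf) {
  denom <- avf + mvf
  out <- sqrt(avf / denom)
  out[denom == 0] <- NaN
  out
}

#' Global MVF calibration factor from a reference ROI
#'
#' Inverts the AVF / g-ratio equations at the reference g-ratio: with
#' `c = (1 - ISOVF) ICVF`, the myelin volume fraction consistent with
#' `g_ref` is `MVF* = c (1 - g_ref^2) / (g_ref^2 + c (1 - g_ref^2))`, and
#' the per-voxel calibration factor is `MVF* / MTsat`. The global factor
#' is the mean over selected voxels (FA above `fa_thresh` inside the
#' ROI); with multiple subjects, voxel means are computed per subject and
#' then averaged with equal subject weights.
#'
#' @param mtsat MTsat grid, or list of grids (one per subject)
#' @param icvf,isovf,fa matching grids or lists
#' @param roi_mask logical grid or list (calibration region)
#' @param g_ref reference g-ratio (default 0.7, splenium convention)
#' @param fa_thresh FA selection threshold (default 0.8)
#' @return list of class `calibration_result`: `alpha_calib`,
#'   `per_voxel` (factors of the first subject), `per_subject`,
#'   `n_voxels`
#' @export
compute_alpha_calib <- function(mtsat, icvf, isovf, fa, roi_mask,
                                g_ref = 0.7, fa_thresh = 0.8) {
  as_list <- function(x) if (is.list(x)) x else list(x)
  mtsat <- as_list(mtsat); icvf <- as_list(icvf); isovf <- as_list(isovf)
  fa <- as_list(fa); roi_mask <- as_list(roi_mask)
  ns <- length(mtsat)
  per_subject <- numeric(ns)
  per_voxel_first <- NULL
  n_vox <- 0L
  for (s in seq_len(ns)) {
    sel <- as.logical(roi_mask[[s]]) & (fa[[s]] > fa_thresh)
    if (!any(sel, na.rm = TRUE)) {
      stop("no calibration voxel passes the FA threshold (subject ", s, ")")
    }
    sel[is.na(sel)] <- FALSE
    ms <- mtsat[[s]][sel]
    cc <- (1 - isovf[[s]][sel]) * icvf[[s]][sel]
    ok <- ms > 0
    if (!any(ok)) stop("all ROI voxels have non-positive MTsat (subject ", s, ")")
    mvf_star <- cc * (1 - g_ref^2) / (g_ref^2 + cc * (1 - g_ref^2))
    factors <- mvf_star[ok] / ms[ok]
    per_subject[s] <- mean(factors)
    if (s == 1) per_voxel_first <- factors
    n_vox <- n_vox + sum(ok)
  }
  structure(list(alpha_calib = mean(per_subject),
                 per_voxel = per_voxel_first,
                 per_subject = per_subject,
                 n_voxels = n_vox, g_ref = g_ref, fa_thresh = fa_thresh),
            class = "calibration_result")
}

#' Fractional anisotropy by log-linear tensor fit
#'
#' Fits the diffusion tensor to `log(S)` using measurements with
#' `b <= b_max` (default 1000 s/mm^2, where the tensor representation is
#' adequate) and returns FA from the eigenvalues, clipped to `[0, 1]`.
#' Voxels with any non-positive signal on the used shells are NaN.
#'
#' @param dwi 4D array
#' @param scheme an [acquisition_scheme()]
#' @param mask 3D logical array
#' @param b_max highest b-value used in the fit
#' @return 3D FA grid (NaN outside mask)
#' @export
compute_fa <- function(dwi, scheme, mask, b_max = 1000) {
  use <- scheme$bvals <= b_max
  nd <- sum(use & !scheme$b0)
  if (nd < 6) stop("need at least 6 diffusion directions at b <= ", b_max)
  b <- scheme$bvals[use]
  g <- scheme$bvecs[use, , drop = FALSE]
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  Xp <- solve(crossprod(X), t(X))
  gs <- dim(mask)
  dm <- dwi_as_matrix(dwi)[, use, drop = FALSE]
  fa <- array(NaN, gs)
  vox <- which(mask)
  for (vl in vox) {
    s <- dm[vl, ]
    if (any(!is.finite(s)) || any(s <= 0)) next
    beta <- Xp %*% log(s)
    D <- matrix(c(beta[2], beta[5], beta[6],
                  beta[5], beta[3], beta[7],
                  beta[6], beta[7], beta[4]), 3, 3)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    fa[vl] <- fa_from_eigenvalues(ev)
  }
  fa
}
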