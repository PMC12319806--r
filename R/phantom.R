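# Synthetic crossing-fiber phantoms with known per-bundle axon and myelin
# ground truth. Everything downstream (operator assembly, NNLS fitting,
# connectomics, tractometry, statistics) is testable against these.

#' Specify a fiber bundle with known microstructure
#'
#' Either give the intra-axonal and myelin cross-sectional areas per
#' streamline directly, or give the bundle g-ratio `g` plus the total
#' fiber cross-sectional area `total_csa`; the two parameterizations are
#' related by `g^2 = axon_csa / (axon_csa + myelin_csa)`.
#'
#' @param id integer bundle id
#' @param centerline n x 2+ matrix of 3D points (world mm)
#' @param n_streamlines number of jittered copies of the centerline
#' @param axon_csa,myelin_csa per-streamline cross-sectional areas (mm^2)
#' @param g bundle g-ratio in (0, 1)
#' @param total_csa per-streamline axon + myelin cross-sectional area (mm^2)
#' @return an object of class `bundle_spec`
#' @export
bundle_spec <- function(id, centerline, n_streamlines = 50,
                        axon_csa = NULL, myelin_csa = NULL,
                        g = NULL, total_csa = NULL) {
  centerline <- rbind_pts(centerline)
  if (is.null(axon_csa)) {
    stopifnot(!is.null(g), !is.null(total_csa), g > 0, g < 1)
    axon_csa <- g^2 * total_csa
    myelin_csa <- (1 - g^2) * total_csa
  }
  stopifnot(axon_csa > 0, myelin_csa >= 0)
  g_true <- sqrt(axon_csa / (axon_csa + myelin_csa))
  if (abs(g_true^2 - axon_csa / (axon_csa + myelin_csa)) > 1e-12) {
    stop("inconsistent g/CSA parameterization")
  }
  structure(list(id = as.integer(id), centerline = centerline,
                 n_streamlines = as.integer(n_streamlines),
                 axon_csa_true = axon_csa, myelin_csa_true = myelin_csa,
                 g_true = g_true),
            class = "bundle_spec")
}

#' Default two-bundle crossing geometry
#'
#' Bundle 1 runs straight along +x through the grid center; bundle 2
#' crosses it in the same axial plane at about 20 degrees. Combined with
#' the default streamline jitter (sd 0.45 voxel) the two tubes share a
#' partial-volume corridor covering most of each bundle's course - the
#' regime in which tractometry is biased while the tract-specific fit,
#' which separates the two orientations, is not. Default g-ratios are
#' 0.60 and 0.80 with a per-streamline fiber cross-section of 0.008 mm^2.
#'
#' @param grid_shape integer triplet
#' @param voxel_size mm
#' @param g g-ratio per bundle (length 2)
#' @param n_streamlines streamlines per bundle
#' @param total_csa per-streamline fiber cross-sectional area (mm^2)
#' @return list of two [bundle_spec()] objects
#' @export
crossing_bundles <- function(grid_shape = c(16, 16, 16), voxel_size = 1,
                             g = c(0.60, 0.80), n_streamlines = 50,
                             total_csa = 0.008) {
  gs <- grid_shape * voxel_size
  mid <- gs / 2 + 0.5 * voxel_size
  x0 <- voxel_size; x1 <- gs[1] - voxel_size
  dy <- 2.55 * voxel_size
  list(
    bundle_spec(1L, rbind(c(x0, mid[2], mid[3]), c(x1, mid[2], mid[3])),
                n_streamlines, g = g[1], total_csa = total_csa),
    bundle_spec(2L, rbind(c(x0, mid[2] - dy, mid[3]), c(x1, mid[2] + dy, mid[3])),
                n_streamlines, g = g[2], total_csa = total_csa)
  )
}

#' Single dense bundle, e.g. for calibration experiments
#'
#' A single coherent bundle along +x at about 80% fiber volume fraction,
#' high enough that the voxel tensor FA exceeds the 0.8 calibration
#' threshold (mimicking the splenium of the corpus callosum).
#'
#' @inheritParams crossing_bundles
#' @param g bundle g-ratio (default the 0.7 calibration reference)
#' @export
single_bundle <- function(grid_shape = c(16, 16, 16), voxel_size = 1,
                          g = 0.7, n_streamlines = 50, total_csa = 0.016) {
  gs <- grid_shape * voxel_size
  mid <- gs / 2 + 0.5 * voxel_size
  list(bundle_spec(1L, rbind(c(voxel_size, mid[2], mid[3]),
                             c(gs[1] - voxel_size, mid[2], mid[3])),
                   n_streamlines, g = g, total_csa = total_csa))
}

#' Phantom specification
#'
#' @param grid_shape integer triplet (default 16^3)
#' @param voxel_size isotropic voxel size in mm
#' @param bundles list of [bundle_spec()]
#' @param n_spurious number of implausible (false-positive) streamlines
#' @param isovf_background isotropic (free-water) volume fraction
#' @param noise_sigma DWI noise standard deviation in signal units (0 =
#'   noiseless)
#' @param seed RNG seed for jitter, spurious geometry, and noise
#' @param jitter_sd perpendicular streamline jitter sd (default 0.45 voxel)
#' @param step polyline sampling step in mm
#' @param mtsat_scale inverse calibration factor used to synthesize the
#'   MTsat grid: MTsat = MVF / mtsat_scale (default 20, the typical
#'   in-vivo calibration factor)
#' @param roi_fa_thresh FA threshold for the calibration ROI
#' @param label_radius radius (mm) of the spherical endpoint node labels
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(16, 16, 16), voxel_size = 1,
                         bundles = crossing_bundles(grid_shape, voxel_size),
                         n_spurious = 10, isovf_background = 0.05,
                         noise_sigma = 0, seed = 1,
                         jitter_sd = 0.45 * voxel_size, step = 0.5,
                         mtsat_scale = 20, roi_fa_thresh = 0.8,
                         label_radius = 1.2 * voxel_size) {
  stopifnot(noise_sigma >= 0, isovf_background >= 0, isovf_background < 1)
  affine <- make_affine(voxel_size)
  lo <- 0; hi <- grid_shape * voxel_size
  for (b in bundles) {
    if (any(b$centerline < lo) || any(sweep(b$centerline, 2, hi) > 0)) {
      stop("bundle ", b$id, " centerline leaves the grid bounding box")
    }
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 affine = affine, bundles = bundles,
                 n_spurious = as.integer(n_spurious),
                 isovf_background = isovf_background,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 jitter_sd = jitter_sd, step = step,
                 mtsat_scale = mtsat_scale, roi_fa_thresh = roi_fa_thresh,
                 label_radius = label_radius),
            class = "phantom_spec")
}

# orthonormal basis perpendicular to a unit vector
perp_basis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  rbind(e1, e2)
}

quadratic_bezier <- function(P, C, Q, n) {
  t <- seq(0, 1, length.out = n)
  b0 <- (1 - t)^2; b1 <- 2 * t * (1 - t); b2 <- t^2
  cbind(b0 * P[1] + b1 * C[1] + b2 * Q[1],
        b0 * P[2] + b1 * C[2] + b2 * Q[2],
        b0 * P[3] + b1 * C[3] + b2 * Q[3])
}

#' Mask of voxels traversed by at least one streamline
#' @param segmap a [voxelize_streamlines()] result
#' @param grid_shape integer triplet
#' @return 3D logical array
#' @export
streamline_mask <- function(segmap, grid_shape) {
  m <- array(FALSE, grid_shape)
  for (e in segmap) {
    if (nrow(e$voxel)) m[voxel_linear_index(e$voxel, grid_shape)] <- TRUE
  }
  m
}

#' Build a synthetic phantom dataset
#'
#' Generates jittered bundle streamlines, spurious arc streamlines
#' connecting random parcellation labels at >= 30 degrees to every bundle
#' orientation, an endpoint parcellation, and the full ground-truth map
#' set (MVF, AVF, ICVF, ISOVF, FA, g, MTsat) obtained by depositing each
#' streamline's axonal and myelin volume (CSA x in-voxel length) into the
#' voxels it traverses.
#'
#' @param spec a [phantom_spec()]
#' @return list of class `phantom`: `streamlines`, `truth`,
#'   `parcellation`, `roi_mask`, `affine`, `segmap`, `spec`
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  gs <- spec$grid_shape
  vs <- spec$voxel_size
  affine <- spec$affine
  voxvol <- voxel_volume(affine)

  streamlines <- list()
  stream_bundle <- integer(0)
  bundle_dirs <- matrix(numeric(0), 0, 3)
  for (b in spec$bundles) {
    cl <- resample_polyline(b$centerline, spec$step)
    u <- cl[nrow(cl), ] - cl[1, ]
    u <- u / sqrt(sum(u^2))
    bundle_dirs <- rbind(bundle_dirs, u)
    E <- perp_basis(u)
    for (k in seq_len(b$n_streamlines)) {
      off <- rnorm(2, sd = spec$jitter_sd)
      pts <- cl + matrix(off[1] * E[1, ] + off[2] * E[2, ],
                         nrow(cl), 3, byrow = TRUE)
      streamlines[[length(streamlines) + 1]] <- pts
      stream_bundle <- c(stream_bundle, b$id)
    }
  }

  # endpoint parcellation: one label per bundle terminus
  parcellation <- array(0L, gs)
  label_radius <- spec$label_radius %||% 0.85 * vs
  label_centers <- list()
  lab <- 0L
  idx <- as.matrix(expand.grid(i = 0:(gs[1] - 1), j = 0:(gs[2] - 1),
                               k = 0:(gs[3] - 1)))
  centers <- voxel_to_world(idx + 0.5, affine)
  for (b in spec$bundles) {
    for (endp in list(b$centerline[1, ], b$centerline[nrow(b$centerline), ])) {
      lab <- lab + 1L
      d2 <- rowSums(sweep(centers, 2, endp)^2)
      sel <- d2 <= label_radius^2
      if (any(parcellation[voxel_linear_index(idx[sel, , drop = FALSE], gs)] != 0)) {
        stop("bundle endpoint label regions overlap; bundles must terminate in distinct labels")
      }
      parcellation[voxel_linear_index(idx[sel, , drop = FALSE], gs)] <- lab
      label_centers[[lab]] <- endp
    }
  }

  # spurious streamlines: arcs between random label pairs whose local
  # orientation in shared voxels differs >= 30 degrees from every bundle
  n_true <- length(streamlines)
  if (spec$n_spurious > 0) {
    for (s in seq_len(spec$n_spurious)) {
      pair <- sample(lab, 2)
      P <- label_centers[[pair[1]]]; Q <- label_centers[[pair[2]]]
      pq <- sqrt(sum((Q - P)^2))
      h <- max(3.5 * vs, 0.6 * pq)
      Cup <- (P + Q) / 2 + c(0, 0, h)
      Cdn <- (P + Q) / 2 - c(0, 0, h)
      zmax <- gs[3] * vs
      C <- if (max(P[3], Q[3]) / 2 + Cup[3] / 2 < zmax - vs) Cup else Cdn
      npt <- max(8L, ceiling(1.3 * pq / spec$step))
      streamlines[[length(streamlines) + 1]] <- quadratic_bezier(P, C, Q, npt)
      stream_bundle <- c(stream_bundle, NA_integer_)
    }
  }

  segmap <- voxelize_streamlines(streamlines, affine, gs)

  # per-streamline microstructure
  bmap <- stats::setNames(spec$bundles, vapply(spec$bundles, `[[`, 1L, "id"))
  axon_csa <- ifelse(is.na(stream_bundle), 0,
                     vapply(stream_bundle, function(i)
                       if (is.na(i)) 0 else bmap[[as.character(i)]]$axon_csa_true,
                       numeric(1)))
  myelin_csa <- ifelse(is.na(stream_bundle), 0,
                       vapply(stream_bundle, function(i)
                         if (is.na(i)) 0 else bmap[[as.character(i)]]$myelin_csa_true,
                         numeric(1)))
  lengths <- vapply(streamlines, streamline_length, numeric(1))

  # ground-truth volume deposition
  axon_vol <- array(0, gs); myelin_vol <- array(0, gs)
  for (i in seq_along(segmap)) {
    e <- segmap[[i]]
    if (!nrow(e$voxel) || axon_csa[i] == 0) next
    vl <- voxel_linear_index(e$voxel, gs)
    for (r in seq_along(vl)) {
      axon_vol[vl[r]] <- axon_vol[vl[r]] + axon_csa[i] * e$length[r]
      myelin_vol[vl[r]] <- myelin_vol[vl[r]] + myelin_csa[i] * e$length[r]
    }
  }
  avf <- axon_vol / voxvol
  mvf <- myelin_vol / voxvol
  isovf <- array(spec$isovf_background, gs)
  tot <- avf + mvf + isovf
  if (any(tot > 1 + 1e-9)) {
    w <- which.max(tot)
    stop(sprintf(
      "total volume fraction exceeds 1 (%.3f at voxel linear index %d): reduce bundle density",
      max(tot), w))
  }
  icvf <- array(0, gs)
  fib <- avf > 0
  icvf[fib] <- avf[fib] / ((1 - mvf[fib]) * (1 - isovf[fib]))
  g <- array(NaN, gs)
  g[fib] <- sqrt(avf[fib] / (avf[fib] + mvf[fib]))
  mtsat <- mvf / spec$mtsat_scale

  # voxel tensor FA of the simulated compartment mixture
  kern <- kernel_params()
  st <- segment_table(segmap, gs)
  tabv <- st$table
  tabv$axvol <- axon_csa[tabv$stream] * tabv$length
  fa <- array(0, gs)
  n_bundles_vox <- array(0L, gs)
  for (vi in seq_along(st$vox_ids)) {
    vl <- st$vox_ids[vi]
    rows <- tabv[tabv$vox_lin == vl, , drop = FALSE]
    cl <- st$clusters[[vi]]
    av_clu <- tapply(rows$axvol, rows$cluster, sum)
    av_v <- sum(rows$axvol)
    n_bundles_vox[vl] <- length(unique(stream_bundle[rows$stream[rows$axvol > 0]]))
    ea_v <- (1 - mvf[vl] - isovf[vl]) * voxvol - av_v
    ea_v <- max(0, ea_v)
    D <- diag(3) * isovf[vl] * voxvol * kern$D_iso[2]
    if (av_v > 0) {
      for (k in seq_len(nrow(cl$dirs))) {
        avk <- if (as.character(k) %in% names(av_clu)) av_clu[[as.character(k)]] else 0
        eak <- ea_v * (if (av_v > 0) avk / av_v else 0)
        u <- cl$dirs[k, ]
        D <- D + avk * kern$D_par * tcrossprod(u) +
          eak * (kern$D_perp * diag(3) + (kern$D_par - kern$D_perp) * tcrossprod(u))
      }
    } else {
      D <- D + ea_v * kern$D_iso[1] * diag(3)
    }
    W <- av_v + ea_v + isovf[vl] * voxvol
    ev <- eigen(D / W, symmetric = TRUE, only.values = TRUE)$values
    fa[vl] <- fa_from_eigenvalues(ev)
  }

  roi_mask <- (n_bundles_vox == 1L) & (fa > spec$roi_fa_thresh)

  # per-edge ground truth
  edges <- do.call(rbind, lapply(spec$bundles, function(b) {
    sel <- which(!is.na(stream_bundle) & stream_bundle == b$id)
    mv <- sum(b$myelin_csa_true * lengths[sel])
    av <- sum(b$axon_csa_true * lengths[sel])
    data.frame(bundle = b$id, node_a = 2L * b$id - 1L, node_b = 2L * b$id,
               MV = mv, AV = av, g = sqrt(av / (av + mv)))
  }))

  truth <- structure(list(
    mvf = mvf, avf = avf, icvf = icvf, isovf = isovf, fa = fa, g = g,
    mtsat = mtsat, affine = affine, voxel_volume = voxvol,
    streamlines = data.frame(stream = seq_along(streamlines),
                             bundle = stream_bundle,
                             axon_csa = axon_csa, myelin_csa = myelin_csa,
                             length = lengths),
    edges = edges, mtsat_scale = spec$mtsat_scale),
    class = "phantom_truth")

  structure(list(streamlines = streamlines, truth = truth,
                 parcellation = parcellation, roi_mask = roi_mask,
                 affine = affine, segmap = segmap, spec = spec),
            class = "phantom")
}

fa_from_eigenvalues <- function(ev) {
  if (all(ev == 0)) return(0)
  mn <- mean(ev)
  f <- sqrt(3 / 2) * sqrt(sum((ev - mn)^2) / sum(ev^2))
  min(1, max(0, f))
}

#' Simulate the multi-shell DWI signal of a phantom
#'
#' Voxel signals (in mm^3 water-volume units) are the sum of per-
#' streamline restricted stick contributions (axon CSA x in-voxel length),
#' per-orientation-cluster hindered zeppelin contributions carrying the
#' extra-axonal volume, and isotropic ball contributions. The total b=0
#' signal of a voxel equals (1 - MVF) x voxel volume: myelin water is
#' invisible. Free water uses the CSF ball (last `D_iso`); voxels without
#' any axonal content put their non-isotropic water into the first
#' (gray-matter-like) ball.
#'
#' @param truth a `phantom_truth` (from [build_phantom()])
#' @param streamlines the phantom streamline list
#' @param scheme an [acquisition_scheme()]
#' @param kernels a [kernel_params()]
#' @param noise_sigma Rician noise sd in signal units (0 = noiseless)
#' @param seed RNG seed for the noise draw
#' @param noise_model "rician" (magnitude MRI) or "gaussian"
#' @param segmap optional precomputed [voxelize_streamlines()] result
#' @return 4D array (x, y, z, measurement)
#' @export
simulate_dwi <- function(truth, streamlines, scheme,
                         kernels = kernel_params(), noise_sigma = 0,
                         seed = 1, noise_model = c("rician", "gaussian"),
                         segmap = NULL) {
  noise_model <- match.arg(noise_model)
  gs <- dim(truth$mvf)
  voxvol <- truth$voxel_volume
  if (is.null(segmap)) segmap <- voxelize_streamlines(streamlines, truth$affine, gs)
  nmeas <- length(scheme$bvals)
  dwi <- array(0, c(gs, nmeas))
  vox_stride <- prod(gs)

  st <- segment_table(segmap, gs)
  tab <- st$table
  axon_csa <- truth$streamlines$axon_csa
  tab$axvol <- axon_csa[tab$stream] * tab$length

  # restricted sticks
  for (r in seq_len(nrow(tab))) {
    if (tab$axvol[r] == 0) next
    u <- c(tab$dx[r], tab$dy[r], tab$dz[r])
    if (sum(u^2) < 1e-20) stop("zero-norm segment direction")
    sig <- tab$axvol[r] * stick_signal(scheme$bvals, scheme$bvecs, u, kernels$D_par)
    dwi[tab$vox_lin[r] + vox_stride * (seq_len(nmeas) - 1)] <-
      dwi[tab$vox_lin[r] + vox_stride * (seq_len(nmeas) - 1)] + sig
  }

  D_gm <- kernels$D_iso[1]
  D_csf <- kernels$D_iso[length(kernels$D_iso)]
  ball_csf <- ball_signal(scheme$bvals, D_csf)
  ball_gm <- ball_signal(scheme$bvals, D_gm)

  av_vox <- numeric(vox_stride)
  if (nrow(tab)) {
    agg <- tapply(tab$axvol, tab$vox_lin, sum)
    av_vox[as.integer(names(agg))] <- as.numeric(agg)
  }
  for (vl in seq_len(vox_stride)) {
    rows_q <- vl + vox_stride * (seq_len(nmeas) - 1)
    iso_v <- truth$isovf[vl] * voxvol
    ea_v <- max(0, (1 - truth$mvf[vl] - truth$isovf[vl]) * voxvol - av_vox[vl])
    dwi[rows_q] <- dwi[rows_q] + iso_v * ball_csf
    if (ea_v <= 0) next
    if (av_vox[vl] > 0) {
      vi <- match(vl, st$vox_ids)
      cl <- st$clusters[[vi]]
      rows <- tab[tab$vox_lin == vl, , drop = FALSE]
      av_clu <- tapply(rows$axvol, rows$cluster, sum)
      for (k in names(av_clu)) {
        if (av_clu[[k]] <= 0) next
        eak <- ea_v * av_clu[[k]] / av_vox[vl]
        sig <- eak * zeppelin_signal(scheme$bvals, scheme$bvecs,
                                     cl$dirs[as.integer(k), ],
                                     kernels$D_par, kernels$D_perp)
        dwi[rows_q] <- dwi[rows_q] + sig
      }
    } else {
      dwi[rows_q] <- dwi[rows_q] + ea_v * ball_gm
    }
  }

  if (noise_sigma > 0) {
    set.seed(seed)
    n <- length(dwi)
    if (noise_model == "rician") {
      dwi <- sqrt((dwi + rnorm(n, sd = noise_sigma))^2 +
                    rnorm(n, sd = noise_sigma)^2)
    } else {
      dwi <- dwi + rnorm(n, sd = noise_sigma)
    }
    dwi <- array(dwi, c(gs, nmeas))
  }
  dwi
}

#' Simulate an MT-weighted spoiled gradient-echo image
#'
#' Algebraic forward model of the MTsat estimator, so that
#' [compute_mtsat()] applied to the output recovers the input saturation
#' exactly in the noiseless case:
#' `S_MTw = S0 a B1 / (1 + (MTsat + (a B1)^2 / 2) T1 / TR)`.
#'
#' @param mtsat MTsat grid (dimensionless fraction)
#' @param s0 equilibrium signal grid (> 0)
#' @param t1 longitudinal relaxation time grid (ms, > 0)
#' @param flip_angle excitation flip angle in radians (default 6 degrees)
#' @param b1 relative transmit field grid (dimensionless, default 1)
#' @param tr repetition time in ms (default 27)
#' @return MT-weighted signal array
#' @export
simulate_mtw <- function(mtsat, s0, t1, flip_angle = 6 * pi / 180, b1 = 1,
                         tr = 27) {
  if (any(s0 <= 0)) stop("S0 must be positive")
  if (any(t1 <= 0)) stop("T1 must be positive")
  a <- flip_angle * b1
  if (any(a <= 0) || any(a >= pi / 2)) {
    stop("effective flip angle must lie in (0, pi/2)")
  }
  denom <- 1 + (mtsat + a^2 / 2) * t1 / tr
  if (any(denom <= 0)) stop("non-positive signal denominator")
  s0 * a / denom
}
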