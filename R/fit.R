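# Non-negative least squares and the three linear solves of the
# tract-specific pipeline: (1) streamline filtering + tract ICVF from raw
# DWI, (2) per-streamline myelin CSA from the MVF map, (3) per-streamline
# true intra-axonal CSA from the myelin-corrected DWI.

#' Non-negative least squares
#'
#' Minimizes `||Ax - y||^2` subject to `x >= 0` by accelerated projected
#' gradient descent (FISTA with adaptive restart), followed by an exact
#' active-set refinement on the identified support so that the KKT
#' conditions hold to solver precision. The refinement uses a relative
#' ridge of 1e-10 on the normal equations, which resolves exactly
#' collinear columns (e.g. duplicated streamlines) by splitting their
#' weight evenly.
#'
#' For large whole-tractogram systems the refinement is better switched
#' off (`polish = FALSE`): duplicated or nearly parallel streamlines make
#' the least-squares optimum a face of the feasible set, and the
#' projected-gradient iterate - like COMMIT's solver - distributes weight
#' across the equivalent streamlines instead of collapsing onto a sparse
#' vertex.
#'
#' @param A design matrix (dense or `Matrix` sparse) or a `linear_system`
#' @param y observation vector (taken from the system if `A` is one)
#' @param tol KKT tolerance (relative to `max(1, ||A'y||_inf)`)
#' @param max_iter maximum FISTA iterations
#' @param polish run the exact active-set refinement (default TRUE)
#' @return list with `x`, `converged`, `iterations`, `kkt`, `objective`
#' @export
solve_nnls <- function(A, y = NULL, tol = 1e-8, max_iter = 5000,
                       polish = TRUE) {
  if (inherits(A, "linear_system")) {
    if (is.null(y)) y <- A$y
    A <- A$A
  }
  if (is.null(y)) stop("no observation vector supplied")
  stopifnot(all(is.finite(y)))
  n <- ncol(A)
  Aty <- as.numeric(Matrix::crossprod(A, y))
  kkt_scale <- max(1, max(abs(Aty)))
  grad_at <- function(x) as.numeric(Matrix::crossprod(A, A %*% x)) - Aty
  kkt_resid <- function(x, g) {
    pos <- x > 0
    max(if (any(pos)) max(abs(g[pos])) else 0,
        if (any(!pos)) max(pmax(0, -g[!pos])) else 0)
  }
  # Lipschitz constant of the gradient via power iteration on A'A
  v <- rep(1 / sqrt(n), n)
  L <- 1
  for (it in 1:30) {
    w <- as.numeric(Matrix::crossprod(A, A %*% v))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) break
    L <- nw
    v <- w / nw
  }
  L <- L * 1.05
  x <- numeric(n); z <- x; tk <- 1
  obj <- function(x) {
    r <- as.numeric(A %*% x) - y
    sum(r^2)
  }
  g <- -Aty
  kkt <- kkt_resid(x, g)
  iters <- 0L
  if (kkt > tol * kkt_scale && L > 0) {
    for (it in seq_len(max_iter)) {
      iters <- it
      gz <- as.numeric(Matrix::crossprod(A, A %*% z)) - Aty
      x_new <- pmax(0, z - gz / L)
      t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      # adaptive restart (gradient scheme)
      if (sum(gz * (x_new - x)) > 0) {
        z <- x_new; t_new <- 1
      } else {
        z <- x_new + ((tk - 1) / t_new) * (x_new - x)
      }
      x <- x_new; tk <- t_new
      if (it %% 20 == 0 || it == max_iter) {
        g <- grad_at(x)
        kkt <- kkt_resid(x, g)
        if (kkt <= tol * kkt_scale) break
      }
    }
  }
  # exact active-set refinement (Lawson-Hanson style, warm-started)
  AtA <- NULL
  get_AtA <- function() {
    if (is.null(AtA)) AtA <<- as.matrix(Matrix::crossprod(A))
    AtA
  }
  if (polish && n <= 4096) {
    S <- which(x > 0)
    x_try <- x
    for (pass in seq_len(2L * n + 10L)) {
      if (length(S)) {
        M <- get_AtA()[S, S, drop = FALSE]
        ridge <- 1e-10 * max(diag(M), 1e-300)
        xs <- tryCatch(solve(M + ridge * diag(length(S)), Aty[S]),
                       error = function(e) NULL)
        if (is.null(xs)) break
        if (any(xs < 0)) {
          xv <- x_try[S]
          bad <- xs < 0
          alpha <- min(xv[bad] / (xv[bad] - xs[bad]))
          xv <- xv + alpha * (xs - xv)
          xv[xv < 1e-14 * max(xv, 1)] <- 0
          x_try[S] <- xv
          x_try[x_try < 0] <- 0
          S <- which(x_try > 0)
          next
        }
        x_try[] <- 0
        x_try[S] <- xs
      }
      g_try <- grad_at(x_try)
      viol <- which(x_try <= 0 & g_try < -tol * kkt_scale)
      if (!length(viol)) break
      S <- sort(unique(c(which(x_try > 0), viol[which.min(g_try[viol])])))
    }
    if (obj(x_try) <= obj(x) + 1e-12 * max(1, obj(x))) x <- x_try
  }
  g <- grad_at(x)
  kkt <- kkt_resid(x, g)
  converged <- kkt <= tol * kkt_scale
  if (!converged) {
    warning("NNLS did not reach the requested KKT tolerance (",
            format(kkt), " > ", format(tol * kkt_scale),
            "); returning best iterate")
  }
  list(x = x, converged = converged, iterations = iters, kkt = kkt,
       objective = obj(x))
}

dwi_as_matrix <- function(dwi) {
  dm <- dim(dwi)
  matrix(dwi, prod(dm[1:3]), dm[4])
}

#' Streamline filtering and tract ICVF from raw DWI
#'
#' Fits the stick-zeppelin-ball forward model to the b0-normalized signal
#' and removes streamlines whose restricted weight is (numerically) zero.
#' The tract ICVF map is the fitted restricted volume over restricted +
#' hindered volume per voxel (the isotropic compartment is excluded from
#' the denominator, as in NODDI's intra-neurite fraction).
#'
#' @param dwi 4D array (x, y, z, measurement), raw signal
#' @param streamlines list of world-mm polylines
#' @param scheme an [acquisition_scheme()]
#' @param kernels a [kernel_params()]
#' @param mask 3D logical array (white matter / fit domain)
#' @param affine 4x4 voxel-to-world transform
#' @param segmap optional precomputed segment map
#' @param zero_threshold streamlines with weight below
#'   `zero_threshold x max(weight)` are treated as zero-weight and removed
#' @param polish exact active-set refinement; off by default for
#'   whole-tractogram systems (see [solve_nnls()])
#' @param ... passed to [solve_nnls()]
#' @return list: `keep` (logical per input streamline), `streamlines`
#'   (the retained ones), `weights` (restricted weight per input
#'   streamline), `icvf` (3D array), `fit` (solver diagnostics)
#' @export
fit_filtering <- function(dwi, streamlines, scheme, kernels, mask, affine,
                          segmap = NULL, zero_threshold = 1e-10,
                          polish = FALSE, ...) {
  gs <- dim(mask)
  voxvol <- voxel_volume(affine)
  if (is.null(segmap)) segmap <- voxelize_streamlines(streamlines, affine, gs)
  dm <- dwi_as_matrix(dwi)
  b0mean <- rowMeans(dm[, scheme$b0, drop = FALSE])
  valid <- mask & array(b0mean > 0, gs)
  n_excl <- sum(mask) - sum(valid)
  if (n_excl > 0) message(n_excl, " masked voxel(s) excluded (non-positive mean b0)")
  sys <- build_dwi_operator(segmap, scheme, kernels, valid)
  ynorm <- dm[sys$vox_lin, , drop = FALSE] / b0mean[sys$vox_lin] * voxvol
  fit <- solve_nnls(sys$A, as.numeric(t(ynorm)), polish = polish, ...)
  w <- fit$x[sys$col_type == "restricted"]
  if (all(w == 0)) stop("degenerate tractogram: all streamline weights are zero")
  keep <- w >= zero_threshold * max(w)

  # per-voxel restricted and hindered fitted volumes
  restr <- numeric(prod(gs)); hind <- numeric(prod(gs))
  tab <- sys$segments$table
  tab <- tab[array(valid, prod(gs))[tab$vox_lin], , drop = FALSE]
  if (nrow(tab)) {
    rv <- tapply(w[tab$stream] * tab$length, tab$vox_lin, sum)
    restr[as.integer(names(rv))] <- as.numeric(rv)
  }
  hsel <- sys$col_type == "hindered"
  if (any(hsel)) {
    hv <- tapply(fit$x[hsel], sys$col_voxel[hsel], sum)
    hind[as.integer(names(hv))] <- as.numeric(hv)
  }
  icvf <- array(0, gs)
  denom <- restr + hind
  nz <- denom > 0
  icvf[nz] <- restr[nz] / denom[nz]
  list(keep = keep, streamlines = streamlines[keep], weights = w,
       icvf = icvf, fit = fit)
}

#' Myelin-correct and normalize the diffusion signal
#'
#' Scales the b0-normalized diffusion signal by `(1 - MVF)` so that the
#' subsequent intra-axonal fit accounts for the (diffusion-invisible)
#' myelin compartment. The output is already normalized; downstream fits
#' must not re-normalize it.
#'
#' @param dwi 4D array, raw signal
#' @param mvf 3D myelin volume fraction grid in `[0, 1)`
#' @param scheme an [acquisition_scheme()]
#' @param mask optional 3D logical array; voxels with non-positive mean b0
#'   inside the mask are set to NA and counted in a message
#' @return 4D array of corrected, dimensionless signal
#' @export
myelin_correct_signal <- function(dwi, mvf, scheme, mask = NULL) {
  if (any(mvf < 0 | mvf >= 1, na.rm = TRUE)) stop("MVF must lie in [0, 1)")
  dm <- dwi_as_matrix(dwi)
  b0mean <- rowMeans(dm[, scheme$b0, drop = FALSE])
  out <- dm / b0mean * (1 - as.numeric(mvf))
  bad <- b0mean <= 0
  if (!is.null(mask)) bad <- bad & as.logical(mask)
  if (any(bad)) {
    message(sum(bad), " voxel(s) excluded from myelin correction (non-positive mean b0)")
    out[bad, ] <- NA_real_
  }
  array(out, dim(dwi))
}

streamline_weights <- function(stream, csa, length, kind) {
  structure(data.frame(stream = stream, csa = csa, length = length,
                       volume = csa * length, kind = kind),
            class = c("streamline_weights", "data.frame"))
}

#' True intra-axonal cross-sectional area per streamline
#'
#' Fits the stick-zeppelin-ball model to the myelin-corrected signal
#' (from [myelin_correct_signal()]); restricted weights are per-streamline
#' intra-axonal cross-sectional areas (mm^2), and the true intra-axonal
#' volume AV is CSA x streamline length.
#'
#' @param corrected_dwi 4D array from [myelin_correct_signal()]
#' @param streamlines filtered streamline list
#' @param scheme,kernels,mask,affine,segmap,polish as in [fit_filtering()]
#' @param ... passed to [solve_nnls()]
#' @return list: `weights` (a `streamline_weights` data frame with
#'   kind "intra_axonal_true"), `fit`
#' @export
fit_true_axonal <- function(corrected_dwi, streamlines, scheme, kernels,
                            mask, affine, segmap = NULL, polish = FALSE,
                            ...) {
  gs <- dim(mask)
  voxvol <- voxel_volume(affine)
  if (is.null(segmap)) segmap <- voxelize_streamlines(streamlines, affine, gs)
  dm <- dwi_as_matrix(corrected_dwi)
  valid <- mask & array(rowSums(!is.finite(dm)) == 0, gs)
  sys <- build_dwi_operator(segmap, scheme, kernels, valid)
  y <- as.numeric(t(dm[sys$vox_lin, , drop = FALSE])) * voxvol
  fit <- solve_nnls(sys$A, y, polish = polish, ...)
  csa <- fit$x[sys$col_type == "restricted"]
  len <- vapply(streamlines, streamline_length, numeric(1))
  list(weights = streamline_weights(seq_along(streamlines), csa, len,
                                    "intra_axonal_true"),
       fit = fit)
}

#' Myelin cross-sectional area per streamline
#'
#' Non-negative fit of per-streamline in-voxel lengths to the myelin
#' volume map: solves `sum_i CSA_i * len_{i,v} = MVF_v x voxel volume`
#' over masked voxels. MV is CSA x streamline length.
#'
#' @param mvf 3D myelin volume fraction grid
#' @param streamlines filtered streamline list
#' @param mask 3D logical array
#' @param affine 4x4 voxel-to-world transform
#' @param segmap optional precomputed segment map
#' @param polish as in [fit_filtering()]
#' @param ... passed to [solve_nnls()]
#' @return list: `weights` (kind "myelin"), `fit`
#' @export
fit_myelin <- function(mvf, streamlines, mask, affine, segmap = NULL,
                       polish = FALSE, ...) {
  gs <- dim(mask)
  if (is.null(segmap)) segmap <- voxelize_streamlines(streamlines, affine, gs)
  sys <- build_myelin_operator(segmap, mvf, mask, voxel_volume(affine))
  fit <- solve_nnls(sys, polish = polish, ...)
  len <- vapply(streamlines, streamline_length, numeric(1))
  list(weights = streamline_weights(seq_along(streamlines), fit$x, len, "myelin"),
       fit = fit)
}
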