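#' @importFrom stats median rnorm runif sd cor setNames
NULL

#' Build a simple RAS affine for an isotropic grid
#'
#' Returns the 4x4 voxel-to-world transform used throughout the package.
#' The convention is the NIfTI one: `affine %*% c(i, j, k, 1)` with 0-based
#' integer indices gives the world-mm coordinate of the *center* of voxel
#' (i, j, k). The default places the corner of voxel (0,0,0) at the world
#' origin, so a grid of shape n spans [0, n * voxel_size] mm.
#'
#' @param voxel_size isotropic voxel edge length in mm
#' @param origin world coordinate of the corner of voxel (0,0,0)
#' @return 4x4 numeric matrix
#' @export
make_affine <- function(voxel_size = 1, origin = c(0, 0, 0)) {
  A <- diag(c(rep(voxel_size, 3), 1))
  A[1:3, 4] <- origin + voxel_size / 2
  A
}

#' World-mm points to continuous voxel coordinates
#'
#' Voxel coordinates follow the half-open-cube convention: voxel (i,j,k)
#' spans `[i, i+1) x [j, j+1) x [k, k+1)`, i.e. the integer part of a
#' coordinate is the 0-based voxel index. (Voxel centers therefore sit at
#' half-integers; this is the NIfTI center convention shifted by 0.5.)
#'
#' @param pts n x 3 matrix of world coordinates (mm)
#' @param affine 4x4 voxel-to-world transform (center convention)
#' @return n x 3 matrix of continuous voxel coordinates
#' @export
world_to_voxel <- function(pts, affine) {
  pts <- rbind_pts(pts)
  R <- affine[1:3, 1:3]
  t <- affine[1:3, 4]
  v <- sweep(pts, 2, t) %*% t(solve(R))
  v + 0.5
}

#' Continuous voxel coordinates back to world mm
#' @param vox n x 3 matrix of voxel coordinates (half-open-cube convention)
#' @param affine 4x4 voxel-to-world transform
#' @return n x 3 matrix of world coordinates
#' @export
voxel_to_world <- function(vox, affine) {
  vox <- rbind_pts(vox) - 0.5
  R <- affine[1:3, 1:3]
  t <- affine[1:3, 4]
  sweep(vox %*% t(R), 2, t, "+")
}

rbind_pts <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

#' Voxel volume implied by an affine
#' @param affine 4x4 voxel-to-world transform
#' @return scalar voxel volume in mm^3
#' @export
voxel_volume <- function(affine) abs(det(affine[1:3, 1:3]))

#' Arc length of a polyline
#' @param pts n x 3 matrix of points (mm)
#' @return total length in mm
#' @export
streamline_length <- function(pts) {
  pts <- rbind_pts(pts)
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Resample a polyline at uniform arc-length spacing
#' @param pts n x 3 matrix (mm)
#' @param step spacing in mm
#' @return m x 3 matrix including both endpoints
#' @export
resample_polyline <- function(pts, step = 0.5) {
  pts <- rbind_pts(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) return(pts[1, , drop = FALSE])
  n <- max(2L, ceiling(L / step) + 1L)
  si <- seq(0, L, length.out = n)
  out <- matrix(NA_real_, n, 3)
  for (d in 1:3) out[, d] <- stats::approx(s, pts[, d], xout = si)$y
  out
}

#' Deterministic quasi-uniform unit directions (Fibonacci sphere)
#'
#' Used to build synthetic multi-shell gradient tables. Directions are
#' spread over the full sphere; antipodal symmetry of the diffusion signal
#' makes hemisphere coverage irrelevant.
#'
#' @param n number of directions
#' @return n x 3 matrix of unit vectors
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Trilinear interpolation of a 3D grid at world coordinates
#'
#' Values live at voxel centers. NA/NaN corners (outside tissue) are
#' excluded and the remaining corner weights renormalized, so samples
#' near a tissue boundary use the defined neighbors only; a sample is
#' NaN when it falls outside the grid or all its corners are undefined.
#'
#' @param vol 3D array
#' @param pts n x 3 world coordinates (mm)
#' @param affine 4x4 voxel-to-world transform
#' @return numeric vector of interpolated values
#' @export
interp_trilinear <- function(vol, pts, affine) {
  v <- world_to_voxel(pts, affine) - 0.5  # now voxel centers at integers
  dm <- dim(vol)
  n <- nrow(v)
  out <- rep(NaN, n)
  i0 <- floor(v)
  f <- v - i0
  ok <- i0[, 1] >= 0 & i0[, 2] >= 0 & i0[, 3] >= 0 &
    i0[, 1] <= dm[1] - 2 & i0[, 2] <= dm[2] - 2 & i0[, 3] <= dm[3] - 2
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  f <- f[ok, , drop = FALSE]
  acc <- 0
  wtot <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    idx <- cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)
    val <- vol[idx]
    fin <- is.finite(val)
    acc <- acc + ifelse(fin, w * val, 0)
    wtot <- wtot + ifelse(fin, w, 0)
  }
  res <- ifelse(wtot > 1e-12, acc / wtot, NaN)
  out[ok] <- res
  out
}

#' Linear (1-based) index of 0-based voxel triplets in an array
#' @keywords internal
voxel_linear_index <- function(vox, grid_shape) {
  1L + vox[, 1] + grid_shape[1] * (vox[, 2] + grid_shape[2] * vox[, 3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
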