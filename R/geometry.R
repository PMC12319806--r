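# Streamline-voxel geometry and assembly of the sparse linear operators
# behind the three NNLS solves (filtering, myelin CSA, true axonal CSA).

#' Multi-shell acquisition scheme
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per measurement
#' @param bvecs n x 3 matrix of gradient directions; unit norm required for
#'   b > `b0_thresh` (b=0 rows may be zero vectors)
#' @param b0_thresh b-values at or below this are treated as b=0
#' @return an object of class `acquisition_scheme`
#' @export
acquisition_scheme <- function(bvals, bvecs, b0_thresh = 10) {
  bvecs <- rbind_pts(bvecs)
  stopifnot(length(bvals) == nrow(bvecs))
  b0 <- bvals <= b0_thresh
  if (!any(b0)) stop("scheme must contain at least one b=0 measurement")
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- !b0 & abs(nrm - 1) > 1e-6
  if (any(bad)) stop("non-unit gradient direction at b > 0 (measurement ",
                     which(bad)[1], ")")
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs, b0 = b0),
            class = "acquisition_scheme")
}

#' The default multi-shell protocol
#'
#' Mirrors the acquisition this pipeline was designed around: 6 b=0 images
#' plus 10 directions at b=300, 30 at b=1000 and 64 at b=2000 s/mm^2.
#' Directions are deterministic quasi-uniform Fibonacci-sphere sets.
#'
#' @return an [acquisition_scheme()]
#' @export
default_scheme <- function() {
  bvals <- c(rep(0, 6), rep(300, 10), rep(1000, 30), rep(2000, 64))
  bvecs <- rbind(matrix(0, 6, 3), fibonacci_directions(10),
                 fibonacci_directions(30), fibonacci_directions(64))
  acquisition_scheme(bvals, bvecs)
}

#' Diffusion kernel parameters for the stick-zeppelin-ball model
#'
#' Defaults are the standard white-matter values: parallel diffusivity of
#' the stick and zeppelin 1.7e-3 mm^2/s, zeppelin perpendicular
#' diffusivity 0.51e-3 mm^2/s, and two isotropic ball diffusivities
#' (1.7e-3 for gray-matter-like and 3.0e-3 for CSF-like partial volume).
#'
#' @param D_par parallel diffusivity (mm^2/s)
#' @param D_perp zeppelin perpendicular diffusivity (mm^2/s)
#' @param D_iso vector of ball diffusivities (mm^2/s)
#' @return an object of class `kernel_params`
#' @export
kernel_params <- function(D_par = 1.7e-3, D_perp = 0.51e-3,
                          D_iso = c(1.7e-3, 3.0e-3)) {
  stopifnot(D_par >= D_perp, D_perp > 0, all(D_iso > 0))
  structure(list(D_par = D_par, D_perp = D_perp, D_iso = D_iso),
            class = "kernel_params")
}

# Closed-form compartment signal kernels (attenuation factors).
stick_signal <- function(bvals, bvecs, dir, D_par) {
  dt <- as.numeric(bvecs %*% dir)
  exp(-bvals * D_par * dt^2)
}
zeppelin_signal <- function(bvals, bvecs, dir, D_par, D_perp) {
  dt <- as.numeric(bvecs %*% dir)
  exp(-bvals * (D_perp + (D_par - D_perp) * dt^2))
}
ball_signal <- function(bvals, D_iso) exp(-bvals * D_iso)

#' Split a streamline into per-voxel segments
#'
#' Converts a world-mm polyline to voxel coordinates (voxel `(i,j,k)`
#' spans the half-open cube `[i,i+1) x ...`), splits every polyline
#' segment exactly at voxel faces, and merges consecutive pieces that
#' share a voxel. The direction of each within-voxel piece is the
#' normalized chord of that piece.
#'
#' @param points n x 3 matrix of world coordinates (mm), n >= 2
#' @param affine 4x4 voxel-to-world transform
#' @param grid_shape integer triplet
#' @return list with `voxel` (m x 3, 0-based indices), `length` (mm),
#'   `dir` (m x 3 unit chords) and `clipped` (TRUE if any part of the
#'   polyline fell outside the grid and was discarded)
#' @export
voxelize_streamline <- function(points, affine, grid_shape) {
  points <- rbind_pts(points)
  if (nrow(points) < 2) stop("a streamline needs at least 2 points")
  u <- world_to_voxel(points, affine)
  nseg <- nrow(points) - 1
  vox_l <- vector("list", nseg); len_l <- vector("list", nseg)
  p0_l <- vector("list", nseg); p1_l <- vector("list", nseg)
  clipped <- FALSE
  for (j in seq_len(nseg)) {
    u1 <- u[j, ]; u2 <- u[j + 1, ]
    wl <- sqrt(sum((points[j + 1, ] - points[j, ])^2))
    if (wl < 1e-12) next
    ts <- c(0, 1)
    for (d in 1:3) {
      lo <- floor(min(u1[d], u2[d])) + 1
      hi <- ceiling(max(u1[d], u2[d])) - 1
      if (hi >= lo && abs(u2[d] - u1[d]) > 1e-14) {
        ts <- c(ts, ((lo:hi) - u1[d]) / (u2[d] - u1[d]))
      }
    }
    ts <- sort(unique(pmin(1, pmax(0, ts))))
    ta <- ts[-length(ts)]; tb <- ts[-1]
    keep <- tb - ta > 1e-12
    ta <- ta[keep]; tb <- tb[keep]
    if (!length(ta)) next
    mids <- outer(rep(1, length(ta)), u1) +
      outer((ta + tb) / 2, u2 - u1)
    vox <- floor(mids)
    inside <- vox[, 1] >= 0 & vox[, 2] >= 0 & vox[, 3] >= 0 &
      vox[, 1] < grid_shape[1] & vox[, 2] < grid_shape[2] & vox[, 3] < grid_shape[3]
    if (any(!inside)) clipped <- TRUE
    if (!any(inside)) next
    seg_vec <- points[j + 1, ] - points[j, ]
    vox_l[[j]] <- vox[inside, , drop = FALSE]
    len_l[[j]] <- wl * (tb - ta)[inside]
    p0_l[[j]] <- outer(rep(1, sum(inside)), points[j, ]) +
      outer(ta[inside], seg_vec)
    p1_l[[j]] <- outer(rep(1, sum(inside)), points[j, ]) +
      outer(tb[inside], seg_vec)
  }
  vox <- do.call(rbind, vox_l)
  if (is.null(vox) || nrow(vox) == 0) {
    return(list(voxel = matrix(integer(0), 0, 3), length = numeric(0),
                dir = matrix(numeric(0), 0, 3), clipped = clipped))
  }
  len <- unlist(len_l)
  p0 <- do.call(rbind, p0_l); p1 <- do.call(rbind, p1_l)
  # merge consecutive pieces in the same voxel
  same <- if (nrow(vox) > 1) {
    c(FALSE, rowSums(abs(vox[-1, , drop = FALSE] -
                           vox[-nrow(vox), , drop = FALSE])) == 0)
  } else FALSE
  grp <- cumsum(!same)
  m <- max(grp)
  mv <- vox[!same, , drop = FALSE]
  ml <- as.numeric(tapply(len, grp, sum))
  first <- which(!same)
  last <- c(first[-1] - 1, nrow(vox))
  chord <- p1[last, , drop = FALSE] - p0[first, , drop = FALSE]
  nrm <- sqrt(rowSums(chord^2))
  # reentrant pieces with near-zero chord: fall back to the longest
  # sub-piece direction
  deg <- nrm < 1e-9
  if (any(deg)) {
    for (g in which(deg)) {
      idx <- first[g]:last[g]
      k <- idx[which.max(len[idx])]
      chord[g, ] <- p1[k, ] - p0[k, ]
      nrm[g] <- sqrt(sum(chord[g, ]^2))
    }
  }
  if (any(nrm < 1e-12)) stop("degenerate streamline piece with zero-norm direction")
  list(voxel = mv, length = ml, dir = chord / nrm, clipped = clipped)
}

#' Voxelize a set of streamlines into a segment map
#' @param streamlines list of n x 3 world-mm matrices
#' @param affine 4x4 voxel-to-world transform
#' @param grid_shape integer triplet
#' @return list of [voxelize_streamline()] results (class `segment_map`)
#' @export
voxelize_streamlines <- function(streamlines, affine, grid_shape) {
  structure(lapply(streamlines, voxelize_streamline, affine = affine,
                   grid_shape = grid_shape),
            class = "segment_map", grid_shape = grid_shape)
}

#' Greedy antipodally-symmetric direction clustering
#'
#' Directions u and -u are identified. Directions are visited in order of
#' decreasing weight and joined to the first existing cluster whose mean
#' direction is within `angle_thresh` degrees; cluster means are
#' weight-averaged.
#'
#' @param dirs m x 3 unit vectors
#' @param weights positive weights (e.g. segment lengths)
#' @param angle_thresh clustering threshold in degrees
#' @return list with `assign` (cluster id per input), `dirs` (k x 3 unit
#'   cluster means) and `weights` (summed member weights)
#' @export
cluster_directions <- function(dirs, weights = rep(1, nrow(dirs)),
                               angle_thresh = 15) {
  dirs <- rbind_pts(dirs)
  m <- nrow(dirs)
  cth <- cos(angle_thresh * pi / 180)
  ord <- order(-weights, seq_len(m))
  cdirs <- matrix(numeric(0), 0, 3)
  csum <- list()
  assign <- integer(m)
  for (i in ord) {
    d <- dirs[i, ]
    hit <- 0L
    if (nrow(cdirs)) {
      dots <- abs(as.numeric(cdirs %*% d))
      j <- which.max(dots)
      if (dots[j] >= cth) hit <- j
    }
    if (hit) {
      s <- sign(sum(cdirs[hit, ] * d)); if (s == 0) s <- 1
      csum[[hit]] <- csum[[hit]] + s * d * weights[i]
      cdirs[hit, ] <- csum[[hit]] / sqrt(sum(csum[[hit]]^2))
      assign[i] <- hit
    } else {
      cdirs <- rbind(cdirs, d)
      csum[[nrow(cdirs)]] <- d * weights[i]
      assign[i] <- nrow(cdirs)
    }
  }
  w <- as.numeric(tapply(weights, assign, sum)[as.character(seq_len(nrow(cdirs)))])
  list(assign = assign, dirs = cdirs, weights = w)
}

# Long-format table of all segment-map entries plus per-voxel orientation
# clusters. Shared between operator assembly and the phantom simulator so
# that both use identical zeppelin orientations.
segment_table <- function(segmap, grid_shape, angle_thresh = 15) {
  n <- length(segmap)
  rows <- lapply(seq_len(n), function(i) {
    e <- segmap[[i]]
    if (!nrow(e$voxel)) return(NULL)
    data.frame(stream = i,
               vox_lin = voxel_linear_index(e$voxel, grid_shape),
               length = e$length,
               dx = e$dir[, 1], dy = e$dir[, 2], dz = e$dir[, 3])
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(stream = integer(0), vox_lin = integer(0),
                                      length = numeric(0), dx = numeric(0),
                                      dy = numeric(0), dz = numeric(0))
  tab$cluster <- NA_integer_
  vox_ids <- sort(unique(tab$vox_lin))
  clusters <- vector("list", length(vox_ids))
  names(clusters) <- as.character(vox_ids)
  for (v in seq_along(vox_ids)) {
    idx <- which(tab$vox_lin == vox_ids[v])
    cl <- cluster_directions(as.matrix(tab[idx, c("dx", "dy", "dz")]),
                             tab$length[idx], angle_thresh)
    tab$cluster[idx] <- cl$assign
    clusters[[v]] <- cl
  }
  list(table = tab, vox_ids = vox_ids, clusters = clusters)
}

#' Assemble the sparse stick-zeppelin-ball forward operator
#'
#' One column block per compartment: a restricted (stick) column per
#' streamline whose entries are `in-voxel length x exp(-b D_par (g.u)^2)`;
#' one hindered (zeppelin) column per voxel orientation cluster (15 degree
#' antipodal clustering of segment directions); and one isotropic (ball)
#' column per masked voxel and ball diffusivity. Rows are ordered masked
#' voxel by masked voxel, measurements contiguous within a voxel.
#'
#' @param segmap a [voxelize_streamlines()] result
#' @param scheme an [acquisition_scheme()]
#' @param kernels a [kernel_params()]
#' @param mask 3D logical array; voxels outside contribute no rows
#' @param angle_thresh hindered orientation clustering threshold (degrees)
#' @return a `linear_system` list: sparse `A`, column bookkeeping
#'   (`col_type`, `col_stream`, `col_voxel`, `col_cluster`, `col_diso`),
#'   masked voxel order `vox_lin`, and the segment/cluster tables
#' @export
build_dwi_operator <- function(segmap, scheme, kernels, mask,
                               angle_thresh = 15) {
  grid_shape <- dim(mask)
  vox_lin <- which(mask)
  if (!length(vox_lin)) stop("empty mask")
  rank_map <- integer(prod(grid_shape))
  rank_map[vox_lin] <- seq_along(vox_lin)
  nmeas <- length(scheme$bvals)
  st <- segment_table(segmap, grid_shape, angle_thresh)
  tab <- st$table
  keep <- rank_map[tab$vox_lin] > 0
  tab_m <- tab[keep, , drop = FALSE]
  n_stream <- length(segmap)

  ii <- list(); jj <- list(); xx <- list(); blk <- 0L
  add <- function(i, j, x) {
    blk <<- blk + 1L
    ii[[blk]] <<- i; jj[[blk]] <<- j; xx[[blk]] <<- x
  }
  qrow <- seq_len(nmeas)
  # restricted columns
  if (nrow(tab_m)) {
    for (r in seq_len(nrow(tab_m))) {
      v <- rank_map[tab_m$vox_lin[r]]
      sig <- tab_m$length[r] *
        stick_signal(scheme$bvals, scheme$bvecs,
                     c(tab_m$dx[r], tab_m$dy[r], tab_m$dz[r]), kernels$D_par)
      add((v - 1L) * nmeas + qrow, rep(tab_m$stream[r], nmeas), sig)
    }
  }
  # hindered columns: per masked voxel, per orientation cluster
  hin_vox <- integer(0); hin_clu <- integer(0)
  col0 <- n_stream
  masked_vox_with_seg <- st$vox_ids[rank_map[st$vox_ids] > 0]
  for (vl in masked_vox_with_seg) {
    cl <- st$clusters[[as.character(vl)]]
    v <- rank_map[vl]
    for (k in seq_len(nrow(cl$dirs))) {
      col0 <- col0 + 1L
      hin_vox <- c(hin_vox, vl); hin_clu <- c(hin_clu, k)
      sig <- zeppelin_signal(scheme$bvals, scheme$bvecs, cl$dirs[k, ],
                             kernels$D_par, kernels$D_perp)
      add((v - 1L) * nmeas + qrow, rep(col0, nmeas), sig)
    }
  }
  n_hin <- length(hin_vox)
  # isotropic columns: every masked voxel, every ball kernel
  n_iso_k <- length(kernels$D_iso)
  iso_cols <- n_stream + n_hin + seq_len(length(vox_lin) * n_iso_k)
  for (k in seq_len(n_iso_k)) {
    sig <- ball_signal(scheme$bvals, kernels$D_iso[k])
    for (v in seq_along(vox_lin)) {
      col <- n_stream + n_hin + (v - 1L) * n_iso_k + k
      add((v - 1L) * nmeas + qrow, rep(col, nmeas), sig)
    }
  }
  ncol_tot <- n_stream + n_hin + length(vox_lin) * n_iso_k
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(length(vox_lin) * nmeas, ncol_tot))
  col_type <- c(rep("restricted", n_stream), rep("hindered", n_hin),
                rep("isotropic", length(vox_lin) * n_iso_k))
  col_stream <- c(seq_len(n_stream), rep(NA_integer_, ncol_tot - n_stream))
  col_voxel <- c(rep(NA_integer_, n_stream), hin_vox,
                 rep(vox_lin, each = n_iso_k))
  col_cluster <- c(rep(NA_integer_, n_stream), hin_clu,
                   rep(NA_integer_, length(vox_lin) * n_iso_k))
  col_diso <- c(rep(NA_real_, n_stream + n_hin),
                rep(kernels$D_iso, times = length(vox_lin)))
  structure(list(A = A, y = NULL, nmeas = nmeas, vox_lin = vox_lin,
                 grid_shape = grid_shape, col_type = col_type,
                 col_stream = col_stream, col_voxel = col_voxel,
                 col_cluster = col_cluster, col_diso = col_diso,
                 segments = st, scheme = scheme, kernels = kernels),
            class = "linear_system")
}

#' Assemble the myelin-deposition operator
#'
#' One row per masked voxel; `A[v, i]` is the in-voxel length (mm) of
#' streamline i in voxel v, and `y[v] = MVF[v] x voxel volume` (mm^3), so
#' the non-negative solution is the per-streamline myelin cross-sectional
#' area in mm^2.
#'
#' @param segmap a [voxelize_streamlines()] result
#' @param mvf 3D myelin volume fraction grid in `[0, 1]`
#' @param mask 3D logical array
#' @param voxel_vol voxel volume in mm^3
#' @return a `linear_system` list with `A` and `y`
#' @export
build_myelin_operator <- function(segmap, mvf, mask, voxel_vol = 1) {
  grid_shape <- dim(mask)
  vox_lin <- which(mask)
  if (!length(vox_lin)) stop("empty mask")
  if (any(mvf < 0 | mvf > 1, na.rm = TRUE)) stop("MVF must lie in [0, 1]")
  rank_map <- integer(prod(grid_shape))
  rank_map[vox_lin] <- seq_along(vox_lin)
  n_stream <- length(segmap)
  ii <- list(); jj <- list(); xx <- list()
  for (i in seq_len(n_stream)) {
    e <- segmap[[i]]
    if (!nrow(e$voxel)) next
    vl <- voxel_linear_index(e$voxel, grid_shape)
    r <- rank_map[vl]
    keep <- r > 0
    if (!any(keep)) next
    # a streamline can revisit a voxel: sum the lengths
    agg <- tapply(e$length[keep], r[keep], sum)
    ii[[i]] <- as.integer(names(agg))
    jj[[i]] <- rep(i, length(agg))
    xx[[i]] <- as.numeric(agg)
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(length(vox_lin), n_stream))
  y <- as.numeric(mvf[vox_lin]) * voxel_vol
  structure(list(A = A, y = y, nmeas = 1L, vox_lin = vox_lin,
                 grid_shape = grid_shape,
                 col_type = rep("restricted", n_stream),
                 col_stream = seq_len(n_stream)),
            class = "linear_system")
}
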