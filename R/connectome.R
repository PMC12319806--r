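# Node-pair aggregation of per-streamline myelin and intra-axonal
# volumes, edge-level g-ratio, and the caliber-percentile and consensus
# cohort filters.

#' Assign streamline endpoints to parcellation nodes
#'
#' Each endpoint maps to the label of its containing voxel; endpoints in
#' background search radially for the nearest labeled voxel center within
#' `search_radius` mm. Streamlines with any unassigned endpoint are
#' dropped (count reported in a message).
#'
#' @param streamlines list of world-mm polylines
#' @param parcellation 3D integer array (0 = background)
#' @param affine 4x4 voxel-to-world transform
#' @param search_radius radial search distance in mm
#' @return data frame with one row per input streamline: `stream`,
#'   `node_a`, `node_b` (`node_a <= node_b`; NA if unassigned), `assigned`
#' @export
assign_edges <- function(streamlines, parcellation, affine,
                         search_radius = 2) {
  gs <- dim(parcellation)
  lab_lin <- which(parcellation > 0)
  lab_idx <- cbind((lab_lin - 1) %% gs[1],
                   ((lab_lin - 1) %/% gs[1]) %% gs[2],
                   (lab_lin - 1) %/% (gs[1] * gs[2]))
  lab_xyz <- voxel_to_world(lab_idx + 0.5, affine)
  lab_val <- parcellation[lab_lin]
  label_at <- function(p) {
    v <- floor(world_to_voxel(p, affine))
    if (all(v >= 0) && all(v < gs)) {
      l <- parcellation[voxel_linear_index(v, gs)]
      if (l > 0) return(l)
    }
    d2 <- rowSums(sweep(lab_xyz, 2, as.numeric(p))^2)
    j <- which.min(d2)
    if (length(j) && d2[j] <= search_radius^2) lab_val[j] else NA_integer_
  }
  n <- length(streamlines)
  a <- integer(n); b <- integer(n)
  for (i in seq_len(n)) {
    s <- rbind_pts(streamlines[[i]])
    a[i] <- label_at(s[1, ])
    b[i] <- label_at(s[nrow(s), ])
  }
  assigned <- !is.na(a) & !is.na(b)
  if (any(!assigned)) {
    message(sum(!assigned), " streamline(s) dropped (unassigned endpoint)")
  }
  data.frame(stream = seq_len(n),
             node_a = ifelse(assigned, pmin(a, b), NA_integer_),
             node_b = ifelse(assigned, pmax(a, b), NA_integer_),
             assigned = assigned)
}

#' Node volumes of a parcellation
#' @param parcellation 3D integer array
#' @param affine 4x4 voxel-to-world transform
#' @return named numeric vector of node volumes (mm^3)
#' @export
node_volumes <- function(parcellation, affine) {
  tab <- table(parcellation[parcellation > 0])
  stats::setNames(as.numeric(tab) * voxel_volume(affine), names(tab))
}

#' Build an MV/AV-weighted connectome
#'
#' Sums per-streamline myelin (MV) and true intra-axonal (AV) volumes
#' over the streamlines connecting each node pair, and derives the
#' edge-level tract-specific g-ratio `sqrt(AV / (AV + MV))`. Tract
#' caliber is the summed intra-axonal plus myelin cross-sectional area;
#' when node volumes are supplied a node-size-corrected caliber
#' (caliber / (vol_a + vol_b)) is added.
#'
#' @param edges data frame from [assign_edges()] (only assigned rows used)
#' @param av_weights,mv_weights `streamline_weights` data frames (from
#'   [fit_true_axonal()] / [fit_myelin()]), indexed like the streamlines
#'   passed to [assign_edges()]
#' @param node_vols optional named vector from [node_volumes()]
#' @return data frame of class `connectome` in long format: `node_a`,
#'   `node_b`, `n_streamlines`, `MV`, `AV`, `caliber`, `g`,
#'   `scaled_caliber`, `g_defined`
#' @export
build_connectome <- function(edges, av_weights, mv_weights,
                             node_vols = NULL) {
  e <- edges[edges$assigned, , drop = FALSE]
  key <- paste(e$node_a, e$node_b, sep = "-")
  ks <- sort(unique(key))
  av <- tapply(av_weights$volume[e$stream], key, sum)[ks]
  mv <- tapply(mv_weights$volume[e$stream], key, sum)[ks]
  cal <- tapply(av_weights$csa[e$stream] + mv_weights$csa[e$stream], key, sum)[ks]
  cnt <- tapply(rep(1, nrow(e)), key, sum)[ks]
  parts <- do.call(rbind, strsplit(ks, "-"))
  out <- data.frame(node_a = as.integer(parts[, 1]),
                    node_b = as.integer(parts[, 2]),
                    n_streamlines = as.integer(cnt),
                    MV = as.numeric(mv), AV = as.numeric(av),
                    caliber = as.numeric(cal))
  out$g <- compute_gratio(out$AV, out$MV)
  out$g_defined <- is.finite(out$g)
  if (!is.null(node_vols)) {
    va <- node_vols[as.character(out$node_a)]
    vb <- node_vols[as.character(out$node_b)]
    out$scaled_caliber <- out$caliber / (as.numeric(va) + as.numeric(vb))
  } else {
    out$scaled_caliber <- NA_real_
  }
  class(out) <- c("connectome", "data.frame")
  out
}

#' Connectome long format to a square matrix
#' @param conn a `connectome` data frame
#' @param metric column to spread ("g", "MV", "AV", "caliber", ...)
#' @param nodes optional node label vector (default: labels present)
#' @return symmetric matrix with NA off-edges
#' @export
connectome_matrix <- function(conn, metric = "g", nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(conn$node_a, conn$node_b)))
  m <- matrix(NA_real_, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  ia <- match(conn$node_a, nodes); ib <- match(conn$node_b, nodes)
  m[cbind(ia, ib)] <- conn[[metric]]
  m[cbind(ib, ia)] <- conn[[metric]]
  m
}

#' Caliber-percentile edge filter across a cohort
#'
#' Pools edge calibers across all supplied connectomes (subjects and
#' sessions), finds the caliber of the `ceil(keep_fraction x n)`-th
#' largest pooled edge, and removes all edges strictly below it in every
#' connectome. Ties at the threshold are kept, so with distinct calibers
#' exactly the bottom `1 - keep_fraction` are removed.
#'
#' @param cohort list of `connectome` data frames
#' @param keep_fraction fraction of pooled edges to retain (default 0.20,
#'   i.e. remove the bottom 80% of tract calibers)
#' @return list with `cohort` (filtered connectomes) and `threshold`
#' @export
caliber_filter <- function(cohort, keep_fraction = 0.20) {
  stopifnot(length(cohort) >= 1)
  pool <- unlist(lapply(cohort, function(c) c$caliber))
  n <- length(pool)
  k <- max(1L, ceiling(keep_fraction * n))
  thr <- sort(pool, decreasing = TRUE)[k]
  list(cohort = lapply(cohort, function(c) {
    out <- c[c$caliber >= thr, , drop = FALSE]
    rownames(out) <- NULL
    out
  }), threshold = thr)
}

#' Consensus edge filter across subjects
#'
#' Retains only edges present (non-zero streamline count) in at least
#' `ceil(min_presence x n_subjects)` subjects; removal is applied to all
#' subjects.
#'
#' @param cohort list of `connectome` data frames, one per subject
#' @param min_presence required presence fraction (default 0.5)
#' @return list with `cohort` and `kept_edges` (data frame of node pairs)
#' @export
consensus_filter <- function(cohort, min_presence = 0.5) {
  need <- ceiling(min_presence * length(cohort))
  keys <- lapply(cohort, function(c) {
    unique(paste(c$node_a[c$n_streamlines > 0],
                 c$node_b[c$n_streamlines > 0], sep = "-"))
  })
  tab <- table(unlist(keys))
  kept <- names(tab)[tab >= need]
  out <- lapply(cohort, function(c) {
    k <- paste(c$node_a, c$node_b, sep = "-")
    r <- c[k %in% kept, , drop = FALSE]
    rownames(r) <- NULL
    r
  })
  parts <- do.call(rbind, strsplit(kept, "-"))
  kept_df <- if (length(kept)) {
    data.frame(node_a = as.integer(parts[, 1]), node_b = as.integer(parts[, 2]))
  } else data.frame(node_a = integer(0), node_b = integer(0))
  list(cohort = out, kept_edges = kept_df)
}

#' Matrix density of a connectome
#' @param conn a `connectome` data frame
#' @param n_nodes total number of parcellation nodes
#' @return fraction of possible undirected edges present
#' @export
matrix_density <- function(conn, n_nodes) {
  nrow(conn) / (n_nodes * (n_nodes - 1) / 2)
}

#' Compare voxel, tractometry and tract-specific g in single-fiber ROIs
#'
#' For each ROI (restricted to voxels with FA above `fa_thresh`):
#' the median voxel g-ratio, the median of the tractometry per-streamline
#' medians over streamlines traversing the ROI, and the tract-specific
#' aggregate g of those same streamlines (from their summed AV and MV).
#'
#' @param g_map volumetric g-ratio grid
#' @param fa FA grid
#' @param roi_masks list of 3D logical arrays
#' @param streamlines list of world-mm polylines
#' @param affine 4x4 voxel-to-world transform
#' @param tractometry_medians per-streamline tractometry medians
#'   (from [tractometry_medians()])
#' @param av_weights,mv_weights `streamline_weights` data frames
#' @param fa_thresh single-fiber FA threshold (default 0.7)
#' @param segmap optional precomputed segment map
#' @return data frame: one row per ROI with `voxel_median`,
#'   `tractometry_median`, `tract_specific_g`, `n_voxels`, `n_streamlines`
#' @export
single_fiber_roi_compare <- function(g_map, fa, roi_masks, streamlines,
                                     affine, tractometry_medians,
                                     av_weights, mv_weights,
                                     fa_thresh = 0.7, segmap = NULL) {
  gs <- dim(g_map)
  if (is.null(segmap)) segmap <- voxelize_streamlines(streamlines, affine, gs)
  out <- lapply(seq_along(roi_masks), function(r) {
    sel <- as.logical(roi_masks[[r]]) & (fa > fa_thresh)
    sel[is.na(sel)] <- FALSE
    if (!any(sel)) {
      return(data.frame(roi = r, voxel_median = NaN, tractometry_median = NaN,
                        tract_specific_g = NaN, n_voxels = 0L,
                        n_streamlines = 0L))
    }
    sel_lin <- which(array(sel, gs))
    traversing <- which(vapply(segmap, function(e) {
      nrow(e$voxel) > 0 &&
        any(voxel_linear_index(e$voxel, gs) %in% sel_lin)
    }, logical(1)))
    av <- sum(av_weights$volume[traversing])
    mv <- sum(mv_weights$volume[traversing])
    data.frame(roi = r,
               voxel_median = median(g_map[sel_lin], na.rm = TRUE),
               tractometry_median = median(tractometry_medians[traversing],
                                           na.rm = TRUE),
               tract_specific_g = compute_gratio(av, mv),
               n_voxels = length(sel_lin),
               n_streamlines = length(traversing))
  })
  do.call(rbind, out)
}
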