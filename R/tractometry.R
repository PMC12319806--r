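# Conventional tractometry comparator: sample a volumetric g-ratio map
# along each streamline, take the per-streamline median, and average the
# medians per connectome edge.

#' Sample a volumetric map along a streamline
#'
#' Resamples the streamline at uniform arc length (default 0.5 mm, the
#' tractography step size) and interpolates the grid trilinearly at each
#' point. NaN samples (outside tissue or outside the grid) are excluded.
#'
#' @param g_map 3D grid (e.g. a g-ratio map, NaN outside tissue)
#' @param streamline n x 3 world-mm polyline
#' @param affine 4x4 voxel-to-world transform
#' @param step sampling step in mm
#' @return numeric vector of valid samples; attribute `all_na` flags
#'   streamlines with no valid sample
#' @export
sample_along <- function(g_map, streamline, affine, step = 0.5) {
  pts <- resample_polyline(streamline, step)
  v <- interp_trilinear(g_map, pts, affine)
  out <- v[is.finite(v)]
  attr(out, "all_na") <- length(out) == 0
  out
}

#' Per-streamline tractometry medians
#' @param g_map 3D grid
#' @param streamlines list of polylines
#' @param affine 4x4 voxel-to-world transform
#' @param step sampling step in mm
#' @return numeric vector (NaN for streamlines with no valid sample)
#' @export
tractometry_medians <- function(g_map, streamlines, affine, step = 0.5) {
  vapply(streamlines, function(s) {
    v <- sample_along(g_map, s, affine, step)
    if (length(v)) median(v) else NaN
  }, numeric(1))
}

#' Edge-level tractometry
#'
#' The tractometry value of an edge is the arithmetic mean of the
#' per-streamline medians over the streamlines connecting the node pair.
#' Streamlines must already be filtered identically to the tract-specific
#' pipeline for the comparison to be equitable.
#'
#' @param medians per-streamline medians (from [tractometry_medians()])
#' @param edges data frame from [assign_edges()]
#' @return data frame of class `tractometry_result`: `node_a`, `node_b`,
#'   `n_streamlines`, `g`
#' @export
edge_tractometry <- function(medians, edges) {
  e <- edges[edges$assigned, , drop = FALSE]
  key <- paste(e$node_a, e$node_b, sep = "-")
  ks <- sort(unique(key))
  gm <- tapply(medians[e$stream], key, function(v) mean(v[is.finite(v)]))[ks]
  cnt <- tapply(rep(1, nrow(e)), key, sum)[ks]
  parts <- do.call(rbind, strsplit(ks, "-"))
  structure(data.frame(node_a = as.integer(parts[, 1]),
                       node_b = as.integer(parts[, 2]),
                       n_streamlines = as.integer(cnt),
                       g = as.numeric(gm)),
            class = c("tractometry_result", "data.frame"))
}
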