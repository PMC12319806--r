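# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# Exhaustive active-set enumeration for NNLS: try every subset of columns,
# solve the unconstrained least-squares problem on the subset, keep
# feasible (non-negative) candidates, return the best.
enumerate_nnls <- function(A, y) {
  A <- as.matrix(A)
  n <- ncol(A)
  stopifnot(n <= 12)
  best_x <- numeric(n)
  best_obj <- sum(y^2)
  for (bits in 1:(2^n - 1)) {
    S <- which(bitwAnd(bits, 2^(seq_len(n) - 1)) > 0)
    As <- A[, S, drop = FALSE]
    xs <- tryCatch(qr.solve(As, y), error = function(e) NULL)
    if (is.null(xs) || any(xs < -1e-12)) next
    obj <- sum((As %*% pmax(xs, 0) - y)^2)
    if (obj < best_obj - 1e-14) {
      best_obj <- obj
      best_x <- numeric(n)
      best_x[S] <- pmax(xs, 0)
    }
  }
  list(x = best_x, objective = best_obj)
}

# Dense supersampling oracle for streamline-voxel intersection: walk the
# polyline in tiny steps and accumulate step lengths per voxel.
supersample_voxel_lengths <- function(points, affine, grid_shape, n = 1e4) {
  pts <- do.call(rbind, lapply(seq_len(nrow(points) - 1), function(j) {
    t <- seq(0, 1, length.out = ceiling(n / (nrow(points) - 1)))
    outer(1 - t, points[j, ]) + outer(t, points[j + 1, ])
  }))
  seg_mid <- (pts[-1, , drop = FALSE] + pts[-nrow(pts), , drop = FALSE]) / 2
  seg_len <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2))
  v <- floor(tractgr::world_to_voxel(seg_mid, affine))
  key <- paste(v[, 1], v[, 2], v[, 3])
  tapply(seg_len, key, sum)
}

# Mean-squares ICC(2,1) via R's ANOVA machinery (independent of the
# package's direct sum-of-squares implementation).
icc21_anova <- function(x1, x2) {
  d <- data.frame(y = c(x1, x2),
                  target = factor(rep(seq_along(x1), 2)),
                  rater = factor(rep(1:2, each = length(x1))))
  av <- summary(stats::aov(y ~ target + rater, data = d))[[1]]
  msr <- av["target", "Mean Sq"]
  msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  n <- length(x1); k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
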