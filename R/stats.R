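# Repeatability and variability analytics: scan-rescan ICC, Bland-Altman
# limits of agreement, coefficient of variation, z-scored network
# summaries, cross-technique correlation, and the mixed-effects
# caliber/length model.

#' Scan-rescan intraclass correlation, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement, from
#' the standard mean-squares decomposition of the n x 2 table.
#'
#' @param scan1,scan2 paired edge values (same length, n >= 3)
#' @return ICC estimate (NaN if total variance is zero)
#' @export
icc_scan_rescan <- function(scan1, scan2) {
  ok <- is.finite(scan1) & is.finite(scan2)
  x <- cbind(scan1[ok], scan2[ok])
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("need at least 3 paired observations")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0) return(NaN)
  (msr - mse) / denom
}

#' Bland-Altman limits of agreement (percent of pairwise mean)
#'
#' Differences are expressed as a percentage of the pairwise mean; limits
#' are `mean difference +/- 1.96 sd`.
#'
#' @param a,b paired values
#' @return list: `mean_diff`, `lower`, `upper` (all in %), `diffs`,
#'   `degenerate` (TRUE when n < 2, where the sd is undefined)
#' @export
bland_altman <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  d <- (a - b) / ((a + b) / 2) * 100
  if (length(d) < 2) {
    return(list(mean_diff = if (length(d)) mean(d) else NaN,
                lower = NaN, upper = NaN, diffs = d, degenerate = TRUE))
  }
  m <- mean(d); s <- sd(d)
  list(mean_diff = m, lower = m - 1.96 * s, upper = m + 1.96 * s,
       diffs = d, degenerate = FALSE)
}

#' Coefficient of variation across subjects, per edge
#'
#' @param values edges x subjects matrix (scan/rescan already averaged
#'   per subject)
#' @return numeric vector `sd/mean` per edge (NaN where the mean is 0)
#' @export
cova <- function(values) {
  values <- as.matrix(values)
  m <- apply(values, 1, mean, na.rm = TRUE)
  s <- apply(values, 1, sd, na.rm = TRUE)
  out <- s / m
  out[m == 0] <- NaN
  out
}

#' Aggregate per-edge values to network pairs
#' @param edge_values numeric vector, one per edge
#' @param node_a,node_b edge node labels
#' @param network named vector mapping node label to network name
#' @return data frame `net_a`, `net_b`, `value` (mean over member edges)
#' @export
aggregate_by_network <- function(edge_values, node_a, node_b, network) {
  na <- network[as.character(node_a)]
  nb <- network[as.character(node_b)]
  key <- paste(pmin(na, nb), pmax(na, nb), sep = "|")
  agg <- tapply(edge_values, key, mean, na.rm = TRUE)
  parts <- do.call(rbind, strsplit(names(agg), "|", fixed = TRUE))
  data.frame(net_a = parts[, 1], net_b = parts[, 2], value = as.numeric(agg))
}

#' Aggregate per-edge values to nodes
#' @inheritParams aggregate_by_network
#' @return named vector: mean over all edges touching each node
#' @export
aggregate_by_node <- function(edge_values, node_a, node_b) {
  nodes <- sort(unique(c(node_a, node_b)))
  stats::setNames(vapply(nodes, function(n) {
    mean(edge_values[node_a == n | node_b == n], na.rm = TRUE)
  }, numeric(1)), nodes)
}

#' Global z-scoring of cohort edge values
#'
#' One mean and one standard deviation are computed across all edges and
#' all subjects (per technique), and applied everywhere.
#'
#' @param values numeric vector or edges x subjects matrix
#' @return z-scored object of the same shape (all zero for constant data)
#' @export
zscore_edges <- function(values) {
  m <- mean(values, na.rm = TRUE)
  s <- sd(as.numeric(values), na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    values[] <- ifelse(is.na(values), NA, 0)
    return(values)
  }
  (values - m) / s
}

#' Per-edge correlation between two techniques
#'
#' Pearson correlation across subjects of the tractometry and
#' tract-specific values of each edge.
#'
#' @param x,y edges x subjects matrices (matching rows/columns)
#' @return list: `per_edge` correlations, `mean` (mean over finite edges)
#' @export
cross_technique_correlation <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(all(dim(x) == dim(y)))
  per_edge <- vapply(seq_len(nrow(x)), function(i) {
    ok <- is.finite(x[i, ]) & is.finite(y[i, ])
    if (sum(ok) < 3) return(NaN)
    suppressWarnings(cor(x[i, ok], y[i, ok]))
  }, numeric(1))
  list(per_edge = per_edge, mean = mean(per_edge[is.finite(per_edge)]))
}

#' Mixed-effects model of g-ratio on caliber and length
#'
#' REML fit of
#' `g ~ caliber + length + (1 + length | subject)`:
#' fixed effects for (node-volume-scaled) tract caliber and tract length,
#' a random intercept per subject and a random length slope per subject.
#' If the random-effects covariance is singular the model falls back to a
#' random intercept only (flagged). The "adjusted" g-ratios returned for
#' plotting against one predictor have the random effects and the other
#' fixed effect removed.
#'
#' @param data data frame with columns `g`, `caliber`, `length`,
#'   `subject`
#' @return list of class `mixed_model_result`: `beta` (named fixed
#'   effects), `se`, `ci` (95%), `p` (normal approximation), `ranef`
#'   (per-subject intercept/slope), `sigma`, `r2_marginal`,
#'   `r2_adjusted`, `adjusted_g_caliber`, `adjusted_g_length`,
#'   `fallback`, `model`
#' @export
fit_mixed_model <- function(data) {
  stopifnot(all(c("g", "caliber", "length", "subject") %in% names(data)))
  if (length(unique(data$subject)) < 2) stop("need at least 2 subjects")
  data$subject <- factor(data$subject)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            optCtrl = list(xtol_abs = 1e-8, ftol_abs = 1e-8))
  fit <- suppressWarnings(
    lme4::lmer(g ~ caliber + length + (1 + length | subject),
               data = data, REML = TRUE, control = ctrl))
  fallback <- FALSE
  if (lme4::isSingular(fit, tol = 1e-5)) {
    fit <- suppressWarnings(
      lme4::lmer(g ~ caliber + length + (1 | subject),
                 data = data, REML = TRUE, control = ctrl))
    fallback <- TRUE
  }
  beta <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(vc))
  ci <- cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se)
  p <- 2 * stats::pnorm(-abs(beta / se))
  re <- lme4::ranef(fit)$subject
  u0 <- stats::setNames(re[["(Intercept)"]], rownames(re))
  u1 <- if ("length" %in% colnames(re)) {
    stats::setNames(re[["length"]], rownames(re))
  } else stats::setNames(rep(0, nrow(re)), rownames(re))
  subj <- as.character(data$subject)
  rand_part <- u0[subj] + u1[subj] * data$length
  # marginal R2 (fixed effects only) and its adjusted version
  yhat_fix <- beta[1] + beta[2] * data$caliber + beta[3] * data$length
  var_f <- stats::var(yhat_fix)
  vc_re <- lme4::VarCorr(fit)
  var_r <- mean((rand_part - mean(rand_part))^2)
  var_e <- stats::sigma(fit)^2
  r2m <- var_f / (var_f + var_r + var_e)
  n <- nrow(data); pfx <- 2
  r2adj <- 1 - (1 - r2m) * (n - 1) / (n - pfx - 1)
  structure(list(
    beta = beta, se = se, ci = ci, p = p,
    ranef = data.frame(subject = rownames(re), u0 = as.numeric(u0),
                       u1 = as.numeric(u1)),
    sigma = stats::sigma(fit), r2_marginal = r2m, r2_adjusted = r2adj,
    adjusted_g_caliber = data$g - beta[3] * data$length - rand_part,
    adjusted_g_length = data$g - beta[2] * data$caliber - rand_part,
    fallback = fallback, model = fit),
    class = "mixed_model_result")
}

#' Simulate an edge table from the caliber/length mixed model
#'
#' Generative counterpart of [fit_mixed_model()] for calibration and
#' recovery experiments: draws per-subject random intercepts and length
#' slopes, per-edge calibers (log-normal) and lengths (uniform 10-200 mm,
#' the tractography length bounds), and Gaussian residuals.
#'
#' @param n_subjects,n_edges cohort dimensions
#' @param beta fixed effects `c(intercept, caliber, length)`
#' @param sd_u0 random intercept sd
#' @param sd_u1 random length-slope sd
#' @param sigma residual sd
#' @param seed RNG seed
#' @return data frame with `g`, `caliber`, `length`, `subject`
#' @export
simulate_edge_table <- function(n_subjects = 20, n_edges = 200,
                                beta = c(0.70, -7.46e-3, 4.04e-4),
                                sd_u0 = 0.02, sd_u1 = 1e-4, sigma = 0.03,
                                seed = 1) {
  set.seed(seed)
  u0 <- rnorm(n_subjects, sd = sd_u0)
  u1 <- rnorm(n_subjects, sd = sd_u1)
  out <- lapply(seq_len(n_subjects), function(s) {
    caliber <- exp(rnorm(n_edges, log(3), 0.5))
    len <- runif(n_edges, 10, 200)
    g <- beta[1] + beta[2] * caliber + beta[3] * len +
      u0[s] + u1[s] * len + rnorm(n_edges, sd = sigma)
    data.frame(g = g, caliber = caliber, length = len, subject = s)
  })
  do.call(rbind, out)
}
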