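make_conn <- function(node_a, node_b, caliber, n = 1, g = 0.7) {
  structure(data.frame(node_a = node_a, node_b = node_b,
                       n_streamlines = n, MV = 1, AV = 1,
                       caliber = caliber, g = g, g_defined = TRUE,
                       scaled_caliber = NA_real_),
            class = c("connectome", "data.frame"))
}

test_that("endpoints map to labels with a 2 mm radial fallback", {
  aff <- make_affine(1)
  gs <- c(8, 8, 8)
  parc <- array(0L, gs)
  parc[2, 2, 2] <- 5L   # voxel spans [1,2)^3, center (1.5,1.5,1.5)
  parc[7, 7, 7] <- 9L
  sl <- list(rbind(c(1.5, 1.5, 1.5), c(6.5, 6.5, 6.5)),   # inside labels
             rbind(c(1.5, 1.5, 3.2), c(6.5, 6.5, 6.5)),   # bg, within 2 mm
             rbind(c(4.5, 1.5, 7.5), c(6.5, 6.5, 6.5)))   # bg, too far
  ed <- suppressMessages(assign_edges(sl, parc, aff))
  expect_equal(ed$node_a[1], 5L); expect_equal(ed$node_b[1], 9L)
  # brute-force nearest-label oracle for the second endpoint
  lab_pos <- rbind(c(1.5, 1.5, 1.5), c(6.5, 6.5, 6.5))
  d <- sqrt(rowSums(sweep(lab_pos, 2, c(1.5, 1.5, 3.2))^2))
  expect_true(min(d) <= 2 && which.min(d) == 1)
  expect_equal(ed$node_a[2], 5L)
  expect_false(ed$assigned[3])
  expect_true(is.na(ed$node_a[3]))
})

test_that("edge aggregation and g computation match hand arithmetic", {
  ed <- data.frame(stream = 1:3, node_a = c(1, 1, 1), node_b = c(2, 2, 3),
                   assigned = TRUE)
  av <- tractgr:::streamline_weights(1:3, csa = c(0.05, 0.05, 0.02),
                                     length = c(10, 10, 5),
                                     kind = "intra_axonal_true")
  mv <- tractgr:::streamline_weights(1:3, csa = c(0.03, 0.03, 0.01),
                                     length = c(10, 10, 5), kind = "myelin")
  nv <- c(`1` = 10, `2` = 30, `3` = 20)
  conn <- build_connectome(ed, av, mv, nv)
  e12 <- conn[conn$node_a == 1 & conn$node_b == 2, ]
  expect_equal(e12$AV, 1.0); expect_equal(e12$MV, 0.6)
  expect_equal(e12$g, sqrt(1 / 1.6), tolerance = 1e-12)
  expect_equal(e12$caliber, 0.16)
  expect_equal(e12$scaled_caliber, 0.16 / 40)
  expect_equal(e12$n_streamlines, 2L)

  # single-streamline worked case: MV 0.3, AV 0.5 -> g = sqrt(0.5/0.8)
  ed1 <- data.frame(stream = 1, node_a = 1, node_b = 2, assigned = TRUE)
  av1 <- tractgr:::streamline_weights(1, 0.05, 10, "intra_axonal_true")
  mv1 <- tractgr:::streamline_weights(1, 0.03, 10, "myelin")
  c1 <- build_connectome(ed1, av1, mv1)
  expect_equal(c1$g, sqrt(0.5 / 0.8), tolerance = 1e-12)

  # splitting volume among duplicate streamlines leaves g unchanged
  ed2 <- data.frame(stream = 1:2, node_a = 1, node_b = 2, assigned = TRUE)
  av2 <- tractgr:::streamline_weights(1:2, c(0.025, 0.025), 10,
                                      "intra_axonal_true")
  mv2 <- tractgr:::streamline_weights(1:2, c(0.015, 0.015), 10, "myelin")
  expect_equal(build_connectome(ed2, av2, mv2)$g, c1$g, tolerance = 1e-12)

  # AV + MV = 0: edge retained, g undefined
  av0 <- tractgr:::streamline_weights(1, 0, 10, "intra_axonal_true")
  mv0 <- tractgr:::streamline_weights(1, 0, 10, "myelin")
  c0 <- build_connectome(ed1, av0, mv0)
  expect_equal(nrow(c0), 1L)
  expect_true(is.nan(c0$g) && !c0$g_defined)
})

test_that("caliber filter removes the bottom 80 percent of pooled calibers", {
  # calibers 1..10, keep 0.2 -> {9, 10} survive
  cc <- make_conn(rep(1, 10), 2:11, caliber = 1:10)
  out <- caliber_filter(list(cc))
  expect_equal(sort(out$cohort[[1]]$caliber), c(9, 10))
  expect_equal(out$threshold, 9)

  # 100 pooled distinct calibers across 4 subjects -> exactly 20 survive
  set.seed(8)
  cal <- sample(seq(0.01, 1, length.out = 100))
  cohort <- lapply(0:3, function(s) {
    make_conn(rep(1, 25), 2:26, caliber = cal[s * 25 + 1:25])
  })
  out2 <- caliber_filter(cohort)
  expect_equal(sum(vapply(out2$cohort, nrow, integer(1))), 20L)

  # all calibers tied at the threshold: everything kept
  cc3 <- make_conn(rep(1, 10), 2:11, caliber = rep(3, 10))
  expect_equal(nrow(caliber_filter(list(cc3))$cohort[[1]]), 10L)
})

test_that("consensus filter applies the ceiling presence rule", {
  edge_in <- function(subj_has) {
    lapply(subj_has, function(h) {
      if (h) make_conn(c(1, 1), c(2, 3), caliber = c(1, 1))
      else make_conn(1, 3, caliber = 1)
    })
  }
  # 10 subjects: edge (1,2) in 5 -> retained; in 4 -> removed
  out5 <- consensus_filter(edge_in(rep(c(TRUE, FALSE), each = 5)))
  expect_true(any(out5$kept_edges$node_b == 2))
  out4 <- consensus_filter(edge_in(c(rep(TRUE, 4), rep(FALSE, 6))))
  expect_false(any(out4$kept_edges$node_b == 2))
  # 7 subjects, 0.5 -> ceil(3.5) = 4 subjects required
  out7a <- consensus_filter(edge_in(c(rep(TRUE, 4), rep(FALSE, 3))))
  expect_true(any(out7a$kept_edges$node_b == 2))
  out7b <- consensus_filter(edge_in(c(rep(TRUE, 3), rep(FALSE, 4))))
  expect_false(any(out7b$kept_edges$node_b == 2))
  # edge present everywhere is always retained
  expect_true(any(consensus_filter(edge_in(rep(TRUE, 6)))$kept_edges$node_b == 2))
})

test_that("matrix density is non-increasing through caliber then consensus", {
  set.seed(21)
  cohort <- lapply(1:6, function(s) {
    ne <- sample(20:30, 1)
    pairs <- t(utils::combn(10, 2))[sample(45, ne), ]
    make_conn(pairs[, 1], pairs[, 2], caliber = runif(ne))
  })
  d0 <- mean(vapply(cohort, matrix_density, numeric(1), n_nodes = 10))
  c1 <- caliber_filter(cohort)$cohort
  d1 <- mean(vapply(c1, matrix_density, numeric(1), n_nodes = 10))
  c2 <- consensus_filter(c1)$cohort
  d2 <- mean(vapply(c2, matrix_density, numeric(1), n_nodes = 10))
  expect_lte(d1, d0)
  expect_lte(d2, d1)
})

test_that("single-fiber ROI comparison behaves on constant and crossing data", {
  # constant g grid: all three methods return the constant
  aff <- make_affine(1)
  gs <- c(6, 6, 6)
  gmap <- array(0.66, gs)
  fa <- array(0.9, gs)
  roi <- array(FALSE, gs); roi[3:4, 3:4, 3:4] <- TRUE
  sl <- list(rbind(c(1, 3.5, 3.5), c(5, 3.5, 3.5)))
  med <- tractometry_medians(gmap, sl, aff)
  av <- tractgr:::streamline_weights(1, 0.05, 4, "intra_axonal_true")
  # myelin CSA consistent with g = 0.66: m = a (1 - g^2) / g^2
  mv <- tractgr:::streamline_weights(1, 0.05 * (1 - 0.66^2) / 0.66^2, 4,
                                     "myelin")
  out <- single_fiber_roi_compare(gmap, fa, list(roi), sl, aff, med, av, mv)
  expect_equal(out$voxel_median, 0.66)
  expect_equal(out$tractometry_median, 0.66)
  expect_equal(out$tract_specific_g, 0.66, tolerance = 1e-12)

  # empty ROI -> NaN
  out0 <- single_fiber_roi_compare(gmap, fa * 0, list(roi), sl, aff, med,
                                   av, mv)
  expect_true(is.nan(out0$voxel_median))

  # crossing phantom: in a pure bundle-1 ROI the tract-specific estimate
  # is closer to the voxel median than tractometry is
  cs <- get_crossing_case()
  ph <- cs$phantom; res <- cs$result
  tr <- ph$truth
  gs2 <- dim(tr$mvf)
  roi2 <- array(FALSE, gs2)
  roi2[2:4, , ] <- tr$avf[2:4, , ] > 0.05 & abs(tr$g[2:4, , ] - 0.6) < 1e-9
  kb <- tr$streamlines$bundle[res$kept]
  cmp <- single_fiber_roi_compare(res$g_map, tr$fa, list(roi2),
                                  res$filtering$streamlines, ph$affine,
                                  res$medians, res$axonal, res$myelin,
                                  fa_thresh = 0.3)
  expect_lt(abs(cmp$tract_specific_g - cmp$voxel_median),
            abs(cmp$tractometry_median - cmp$voxel_median))
})
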