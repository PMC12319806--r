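test_that("voxelization splits segments at voxel faces with exact lengths", {
  aff <- make_affine(1)
  gs <- c(8, 8, 8)

  # fully inside one voxel
  v <- voxelize_streamline(rbind(c(2.1, 2.2, 2.3), c(2.8, 2.2, 2.3)), aff, gs)
  expect_equal(nrow(v$voxel), 1L)
  expect_equal(v$voxel[1, ], c(2, 2, 2))
  expect_equal(v$length, 0.7)
  expect_false(v$clipped)

  # axis-aligned voxel-center to voxel-center: 0.5 mm in each voxel,
  # cross-checked against a dense supersampling oracle
  pts <- rbind(c(2.5, 3.5, 3.5), c(3.5, 3.5, 3.5))
  v <- voxelize_streamline(pts, aff, gs)
  expect_equal(sort(v$length), c(0.5, 0.5))
  oracle <- supersample_voxel_lengths(pts, aff, gs)
  key <- paste(v$voxel[, 1], v$voxel[, 2], v$voxel[, 3])
  expect_equal(as.numeric(oracle[key]), v$length, tolerance = 1e-3)

  # oblique segment against the oracle
  pts <- rbind(c(1.3, 1.7, 2.2), c(5.9, 4.1, 3.3))
  v <- voxelize_streamline(pts, aff, gs)
  oracle <- supersample_voxel_lengths(pts, aff, gs, n = 2e5)
  key <- paste(v$voxel[, 1], v$voxel[, 2], v$voxel[, 3])
  expect_equal(as.numeric(oracle[key]), v$length, tolerance = 1e-4)
})

test_that("in-voxel lengths conserve arc length for random polylines", {
  set.seed(42)
  aff <- make_affine(1.3)
  gs <- c(10, 10, 10)
  for (i in 1:20) {
    pts <- matrix(runif(5 * 3, 2, 10), ncol = 3)
    v <- voxelize_streamline(pts, aff, gs)
    expect_equal(sum(v$length), streamline_length(pts), tolerance = 1e-9)
    expect_true(all(v$length > 0))
    expect_true(all(abs(sqrt(rowSums(v$dir^2)) - 1) < 1e-9))
  }
})

test_that("points outside the grid are clipped and flagged", {
  aff <- make_affine(1)
  v <- voxelize_streamline(rbind(c(-1, 1.5, 1.5), c(2.5, 1.5, 1.5)),
                           aff, c(4, 4, 4))
  expect_true(v$clipped)
  expect_equal(sum(v$length), 2.5, tolerance = 1e-9)  # clipped at x = 0
})

test_that("acquisition scheme validates directions and b0 presence", {
  expect_error(acquisition_scheme(c(1000, 1000), rbind(c(1, 0, 0), c(0, 1, 0))),
               "b=0")
  expect_error(acquisition_scheme(c(0, 1000), rbind(c(0, 0, 0), c(2, 0, 0))),
               "non-unit")
  sch <- acquisition_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(sum(sch$b0), 1L)
})

test_that("direction clustering is antipodal with a 15 degree threshold", {
  d <- rbind(c(1, 0, 0), c(-1, 0, 0),                    # same fiber
             c(cos(10 * pi / 180), sin(10 * pi / 180), 0),  # within 15 deg
             c(0, 0, 1))                                  # distinct
  cl <- cluster_directions(d, weights = c(2, 2, 1, 1))
  expect_equal(length(unique(cl$assign[1:3])), 1L)
  expect_false(cl$assign[4] == cl$assign[1])
  expect_equal(nrow(cl$dirs), 2L)

  # 30 degrees apart: separate clusters
  d2 <- rbind(c(1, 0, 0), c(cos(pi / 6), sin(pi / 6), 0))
  expect_equal(nrow(cluster_directions(d2)$dirs), 2L)
})

test_that("DWI operator entries match closed-form kernels", {
  aff <- make_affine(1)
  gs <- c(3, 3, 3)
  # one streamline crossing the center voxel along x, length 1
  sl <- list(rbind(c(1, 1.5, 1.5), c(2, 1.5, 1.5)))
  sm <- voxelize_streamlines(sl, aff, gs)
  mask <- array(FALSE, gs); mask[2, 2, 2] <- TRUE
  kern <- kernel_params()

  # b0 rows: restricted entries equal the in-voxel length
  sch <- acquisition_scheme(c(0, 2000), rbind(c(0, 0, 0), c(1, 1, 0) / sqrt(2)))
  sys <- build_dwi_operator(sm, sch, kern, mask)
  A <- as.matrix(sys$A)
  expect_equal(A[1, 1], 1.0)

  # stick at 45 degrees to the gradient, b = 2000
  expect_equal(A[2, 1], 1 * exp(-2000 * 1.7e-3 * 0.5), tolerance = 1e-12)

  # zeppelin and ball kernels in the same voxel
  hin <- which(sys$col_type == "hindered")
  expect_equal(A[2, hin], exp(-2000 * (0.51e-3 + (1.7e-3 - 0.51e-3) * 0.5)),
               tolerance = 1e-12)
  iso <- which(sys$col_type == "isotropic")
  expect_equal(sort(A[2, iso]), sort(exp(-2000 * c(1.7e-3, 3.0e-3))),
               tolerance = 1e-12)
  expect_error(build_dwi_operator(sm, sch, kern, array(FALSE, gs)), "empty mask")
})

test_that("identical streamlines produce identical restricted columns and
           removing one changes nothing else", {
  aff <- make_affine(1)
  gs <- c(4, 4, 4)
  sl <- list(rbind(c(0.6, 1.5, 1.5), c(3.4, 1.5, 1.5)),
             rbind(c(0.6, 1.5, 1.5), c(3.4, 1.5, 1.5)),
             rbind(c(1.5, 0.6, 1.5), c(1.5, 3.4, 1.5)))
  sm <- voxelize_streamlines(sl, aff, gs)
  mask <- streamline_mask(sm, gs)
  sch <- default_scheme()
  sys3 <- build_dwi_operator(sm, sch, kernel_params(), mask)
  A3 <- as.matrix(sys3$A)
  expect_equal(A3[, 1], A3[, 2])

  sm2 <- structure(sm[c(1, 3)], class = "segment_map")
  sys2 <- build_dwi_operator(sm2, sch, kernel_params(), mask)
  A2 <- as.matrix(sys2$A)
  expect_equal(sum(sys3$col_type == "restricted") -
                 sum(sys2$col_type == "restricted"), 1L)
  expect_equal(A2[, 1], A3[, 1])
  expect_equal(A2[, 2], A3[, 3])
})

test_that("myelin operator encodes lengths and recovers CSA", {
  aff <- make_affine(1)
  gs <- c(3, 3, 3)
  # worked 1x1 case: length 1 mm, MVF 0.2, voxel 1 mm^3 -> CSA 0.2 mm^2
  sl <- list(rbind(c(1, 1.5, 1.5), c(2, 1.5, 1.5)))
  sm <- voxelize_streamlines(sl, aff, gs)
  mask <- array(FALSE, gs); mask[2, 2, 2] <- TRUE
  mvf <- array(0, gs); mvf[2, 2, 2] <- 0.2
  sys <- build_myelin_operator(sm, mvf, mask)
  expect_equal(as.numeric(sys$A[1, 1]), 1)
  expect_equal(solve_nnls(sys)$x, 0.2, tolerance = 1e-8)

  # disjoint streamlines -> block-diagonal, independent recovery
  sl2 <- list(rbind(c(0.2, 0.5, 0.5), c(0.9, 0.5, 0.5)),
              rbind(c(2.1, 2.5, 2.5), c(2.9, 2.5, 2.5)))
  sm2 <- voxelize_streamlines(sl2, aff, gs)
  mask2 <- streamline_mask(sm2, gs)
  mvf2 <- array(0, gs); mvf2[1, 1, 1] <- 0.07; mvf2[3, 3, 3] <- 0.32
  sys2 <- build_myelin_operator(sm2, mvf2, mask2)
  x <- solve_nnls(sys2)$x
  expect_equal(x, c(0.07 / 0.7, 0.32 / 0.8), tolerance = 1e-8)
  expect_error(build_myelin_operator(sm2, mvf2 + 2, mask2), "0, 1")
})
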