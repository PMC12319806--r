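test_that("volume deposition matches direct bookkeeping", {
  # single straight bundle along +x, one streamline, axon CSA 0.1 mm^2,
  # 1 mm voxels: every fully traversed voxel gains 0.1 mm^3 axonal volume
  b <- bundle_spec(1L, rbind(c(1, 8.5, 8.5), c(15, 8.5, 8.5)),
                   n_streamlines = 1, axon_csa = 0.1, myelin_csa = 0.05)
  ph <- build_phantom(phantom_spec(bundles = list(b), n_spurious = 0,
                                   jitter_sd = 0, seed = 1))
  avf_core <- ph$truth$avf[3:13, 9, 9]
  expect_equal(avf_core, rep(0.1, 11), tolerance = 1e-12)
  expect_equal(ph$truth$g[5, 9, 9], sqrt(0.1 / 0.15), tolerance = 1e-12)

  # two orthogonal bundles crossing in one voxel: the crossing voxel's MVF
  # is the sum of both deposits (direct bookkeeping oracle from segmap)
  b1 <- bundle_spec(1L, rbind(c(1, 8.5, 8.5), c(15, 8.5, 8.5)),
                    n_streamlines = 1, axon_csa = 0.1, myelin_csa = 0.05)
  b2 <- bundle_spec(2L, rbind(c(8.5, 1, 8.5), c(8.5, 15, 8.5)),
                    n_streamlines = 1, axon_csa = 0.08, myelin_csa = 0.04)
  ph2 <- build_phantom(phantom_spec(bundles = list(b1, b2), n_spurious = 0,
                                    jitter_sd = 0, seed = 1))
  gs <- dim(ph2$truth$mvf)
  oracle_mvf <- numeric(prod(gs))
  csa_m <- c(0.05, 0.04)
  for (i in 1:2) {
    e <- ph2$segmap[[i]]
    vl <- tractgr:::voxel_linear_index(e$voxel, gs)
    for (r in seq_along(vl)) {
      oracle_mvf[vl[r]] <- oracle_mvf[vl[r]] + csa_m[i] * e$length[r]
    }
  }
  expect_equal(as.numeric(ph2$truth$mvf), oracle_mvf, tolerance = 1e-12)
  cross <- which(oracle_mvf == max(oracle_mvf))
  expect_equal(ph2$truth$mvf[cross], 0.05 + 0.04, tolerance = 1e-12)
})

test_that("phantom respects its stated invariants", {
  ph <- build_phantom(phantom_spec(seed = 4))
  tr <- ph$truth

  # volume conservation per voxel
  expect_true(all(tr$avf + tr$mvf + tr$isovf <= 1 + 1e-9))
  expect_true(all(tr$avf >= 0 & tr$mvf >= 0))
  expect_true(all(tr$icvf >= 0 & tr$icvf <= 1 + 1e-9))

  # total deposited axonal volume of each true streamline = CSA x length
  gs <- dim(tr$mvf)
  for (i in which(!is.na(tr$streamlines$bundle))[1:10]) {
    e <- ph$segmap[[i]]
    expect_equal(sum(e$length), tr$streamlines$length[i], tolerance = 1e-9)
  }

  # g_true^2 == axon / (axon + myelin) for every bundle
  for (b in ph$spec$bundles) {
    expect_equal(b$g_true^2,
                 b$axon_csa_true / (b$axon_csa_true + b$myelin_csa_true),
                 tolerance = 1e-12)
  }

  # endpoint labels: every true streamline connects its bundle's node pair
  ed <- suppressMessages(assign_edges(ph$streamlines, ph$parcellation,
                                      ph$affine))
  for (b in ph$spec$bundles) {
    sel <- which(tr$streamlines$bundle == b$id)
    expect_true(all(ed$node_a[sel] == 2 * b$id - 1, na.rm = TRUE))
    expect_true(all(ed$node_b[sel] == 2 * b$id, na.rm = TRUE))
  }
})

test_that("overfull voxels are rejected with a diagnostic", {
  b <- bundle_spec(1L, rbind(c(1, 8.5, 8.5), c(15, 8.5, 8.5)),
                   n_streamlines = 50, axon_csa = 0.02, myelin_csa = 0.01)
  expect_error(build_phantom(phantom_spec(bundles = list(b), n_spurious = 0,
                                          jitter_sd = 0.1, seed = 1)),
               "exceeds 1")
})

test_that("phantom and DWI simulation are reproducible and noise-free by default", {
  sp <- phantom_spec(seed = 11)
  ph1 <- build_phantom(sp); ph2 <- build_phantom(sp)
  expect_identical(ph1$truth$mvf, ph2$truth$mvf)
  expect_identical(ph1$streamlines, ph2$streamlines)

  sch <- acquisition_scheme(c(0, 0, 1000), rbind(c(0, 0, 0), c(0, 0, 0),
                                                 c(1, 0, 0)))
  d1 <- simulate_dwi(ph1$truth, ph1$streamlines, sch, segmap = ph1$segmap)
  d2 <- simulate_dwi(ph2$truth, ph2$streamlines, sch, segmap = ph2$segmap)
  expect_identical(d1, d2)

  # b=0: signal equals (1 - MVF) x voxel volume in every voxel
  expect_equal(as.numeric(d1[, , , 1]), as.numeric((1 - ph1$truth$mvf)),
               tolerance = 1e-12)
  expect_identical(d1[, , , 1], d1[, , , 2])
})

test_that("Rician noise bias at SNR > 20 is below 2 percent", {
  # Monte-Carlo with 1e4 b0 draws on a small phantom voxel
  b <- bundle_spec(1L, rbind(c(0.5, 1.5, 1.5), c(2.5, 1.5, 1.5)),
                   n_streamlines = 1, axon_csa = 0.1, myelin_csa = 0.05)
  ph <- build_phantom(phantom_spec(grid_shape = c(3, 3, 3),
                                   bundles = list(b), n_spurious = 0,
                                   jitter_sd = 0, label_radius = 0.5,
                                   seed = 1))
  nrep <- 1e4
  sch <- acquisition_scheme(rep(0, nrep), matrix(0, nrep, 3))
  s_true <- 1 - ph$truth$mvf[2, 2, 2]
  sigma <- s_true / 25  # SNR 25
  d <- simulate_dwi(ph$truth, ph$streamlines, sch, noise_sigma = sigma,
                    seed = 9, segmap = ph$segmap)
  expect_lt(abs(mean(d[2, 2, 2, ]) / s_true - 1), 0.02)
})

test_that("MT-weighted forward model inverts exactly", {
  set.seed(7)
  mtsat <- array(runif(64, 0, 0.06), c(4, 4, 4))
  s0 <- array(runif(64, 800, 1200), c(4, 4, 4))
  t1 <- array(runif(64, 700, 1500), c(4, 4, 4))
  b1 <- array(runif(64, 0.9, 1.1), c(4, 4, 4))
  mtw <- simulate_mtw(mtsat, s0, t1, b1 = b1)
  rec <- compute_mtsat(mtw, s0, t1, b1 = b1)
  expect_equal(rec, mtsat, tolerance = 1e-10)

  # zero-saturation closed form
  a <- 6 * pi / 180
  expect_equal(simulate_mtw(0, 1000, 1000),
               1000 * a / (1 + a^2 * 1000 / (2 * 27)), tolerance = 1e-12)

  # protocol values (flip 6 deg, TR 27 ms): finite positive signal
  sig <- simulate_mtw(seq(0, 0.1, length.out = 11), 1000, 1000)
  expect_true(all(is.finite(sig) & sig > 0))

  expect_error(simulate_mtw(0.01, -5, 1000), "S0")
  expect_error(simulate_mtw(0.01, 1000, 1000, flip_angle = 2), "flip")
})

test_that("spurious streamlines are at least 30 degrees off every bundle
           orientation in shared voxels", {
  ph <- build_phantom(phantom_spec(seed = 5))
  tr <- ph$truth
  gs <- dim(tr$mvf)
  bundle_dirs <- rbind(c(1, 0, 0),
                       {
                         cl <- ph$spec$bundles[[2]]$centerline
                         d <- cl[2, ] - cl[1, ]; d / sqrt(sum(d^2))
                       })
  fiber_vox <- which(tr$avf > 0)
  spur <- which(is.na(tr$streamlines$bundle))
  for (i in spur) {
    e <- ph$segmap[[i]]
    vl <- tractgr:::voxel_linear_index(e$voxel, gs)
    shared <- vl %in% fiber_vox
    if (!any(shared)) next
    for (r in which(shared)) {
      ang <- acos(pmin(1, abs(bundle_dirs %*% e$dir[r, ]))) * 180 / pi
      expect_gte(min(ang), 30 - 1e-6)
    }
  }
})
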