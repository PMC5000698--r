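test_that("stokes-basis inversion recovers a known per-pixel matrix exactly", {
  set.seed(13)
  M <- unclass(random_physical_mueller())
  out <- array(0, c(3, 3, 4, 4))
  basis <- input_state_basis()
  for (k in 1:4) {
    s <- M %*% basis[, k]
    for (c in 1:4) out[, , c, k] <- s[c]
  }
  img <- mueller_from_stokes_basis(out)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(as.numeric(img$planes[2, 2, (i - 1) * 4 + j]), M[i, j],
                 tolerance = 1e-12)
  }
})

test_that("stokes-basis inversion is linear: a depolarizing mixture averages", {
  set.seed(14)
  M1 <- unclass(random_physical_mueller())
  M2 <- unclass(random_physical_mueller())
  basis <- input_state_basis()
  out <- array(0, c(2, 2, 4, 4))
  for (k in 1:4) {
    s <- (M1 %*% basis[, k] + M2 %*% basis[, k]) / 2
    for (c in 1:4) out[, , c, k] <- s[c]
  }
  img <- mueller_from_stokes_basis(out)
  expect_equal(matrix(img$planes[1, 1, ], 4, 4, byrow = TRUE),
               (M1 + M2) / 2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("per-pixel recovery on an 8x8 grid matches a loop-based oracle", {
  set.seed(15)
  basis <- input_state_basis()
  truth <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  out <- array(0, c(8, 8, 4, 4))
  for (i in 1:8) for (j in 1:8) {
    M <- matrix(truth[i, j, ], 4, 4, byrow = TRUE)
    for (k in 1:4) out[i, j, , k] <- M %*% basis[, k]
  }
  img <- mueller_from_stokes_basis(out)
  expect_equal(img$planes, truth, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a singular probing basis is rejected", {
  out <- array(1, c(2, 2, 4, 4))
  bad <- matrix(1, 4, 4)
  expect_error(mueller_from_stokes_basis(out, in_basis = bad), "singular")
})

test_that("degradation sweep reproduces the published parameter ladders", {
  # toilet soap: sphere/cylinder scattering-coefficient pairs
  s1 <- degradation_sweep("toilet_soap", 1)
  expect_equal(s1$sphere$mus, 10)
  expect_equal(s1$cylinder$mus, 70)
  # constant total optical thickness across the sweep
  for (k in 1:7) {
    med <- degradation_sweep("toilet_soap", k)
    expect_equal(med$sphere$mus + med$cylinder$mus, 80)
    expect_equal(med$cylinder$diameter, 1.5)   # geometry untouched
  }
  # color stain net: cylinder diameter / orientation-spread pairs
  s7 <- degradation_sweep("color_stain_net", 7)
  expect_equal(s7$cylinder$diameter, 0.68)
  expect_equal(s7$cylinder$orientation_std, 22)
  expect_equal(s7$sphere$mus, 10)              # split fixed at baseline
  expect_error(degradation_sweep("toilet_soap", 8), "1..7")
  expect_error(degradation_sweep("bleach", 1))
})

test_that("simulation is bit-identical under a repeated seed", {
  med <- medium_config()
  r1 <- run_simulation(med, tiny_detector(), n_photons = 2000, seed = 99)
  r2 <- run_simulation(med, tiny_detector(), n_photons = 2000, seed = 99)
  expect_identical(r1$image$planes, r2$image$planes)
  expect_identical(r1$counts, r2$counts)
  expect_identical(unclass(r1$region_mueller), unclass(r2$region_mueller))
})

test_that("a non-scattering medium detects nothing and masks the image", {
  med <- medium_config(sphere = sphere_species(mus = 1e-9),
                       cylinder = cylinder_species(mus = 1e-9))
  expect_warning(
    res <- run_simulation(med, tiny_detector(), n_photons = 200, seed = 1),
    "masked")
  expect_null(res$image)
  expect_equal(sum(res$n_detected), 0)
  expect_error(medium_config(sphere = sphere_species(mus = 0),
                             cylinder = cylinder_species(mus = 0)),
               "positive")
})

test_that("sphere-only medium yields a block-diagonal region Mueller matrix", {
  med <- medium_config(sphere = sphere_species(mus = 80),
                       cylinder = cylinder_species(mus = 1e-9))
  runs <- lapply(1:3, function(r) {
    run_simulation(med, tiny_detector(), n_photons = 1e5, seed = 200 + r)
  })
  arr <- simplify2array(lapply(runs, function(s) unclass(s$region_mueller)))
  # conservative Monte Carlo standard error: every detected photon carries
  # |S_k| <= S0 = 1, so the pooled region mean has SE <= 1/sqrt(n_detected)
  n_det <- sum(vapply(runs, function(s) min(s$n_detected), numeric(1)))
  se_bound <- 1 / sqrt(n_det)
  off_block <- rbind(c(1, 3), c(1, 4), c(2, 3), c(2, 4),
                     c(3, 1), c(3, 2), c(4, 1), c(4, 2))
  for (k in seq_len(nrow(off_block))) {
    v <- arr[off_block[k, 1], off_block[k, 2], ]
    expect_lt(abs(mean(v)), 3.5 * se_bound)
  }
  # and the diagonal shows the backscattering depolarization signature
  expect_gt(mean(arr[2, 2, ]), 0.3)
})

test_that("the silk baseline shows the aligned-fiber signature", {
  med <- medium_config()   # cylinders along x, 15 degree spread
  sim <- run_simulation(med, detector_config(grid = c(16L, 16L),
                                             extent = 0.4,
                                             acceptance_deg = 20),
                        n_photons = 4e4, seed = 301)
  M <- unclass(sim$region_mueller)
  expect_gt(M[1, 2], 0)           # m12 positive
  expect_gt(M[2, 1], 0)           # m21 positive
  expect_lt(abs(M[1, 3]), M[1, 2] / 5)  # m13 near zero
  expect_lt(abs(M[3, 1]), M[1, 2] / 5)  # m31 near zero
  expect_gt(M[2, 2], M[3, 3])     # anisotropy: m22 exceeds m33
})

test_that("every unmasked pixel satisfies the m11 bound approximately", {
  sim <- run_simulation(medium_config(), tiny_detector(),
                        n_photons = 2e4, seed = 41)
  img <- sim$image
  counts <- sim$counts
  for (k in 2:16) {
    plane <- img$planes[, , k]
    # per-pixel MC standard error ~ 1/sqrt(count); allow 3 SE above 1
    ok <- abs(plane[img$mask]) <= 1 + 3 / sqrt(counts[img$mask]) + 1e-9
    expect_true(all(ok))
  }
})

test_that("fiber-axis off-diagonals shrink as photons grow", {
  med <- medium_config()
  m13 <- vapply(c(2000, 16000), function(n) {
    M <- unclass(run_simulation(med, tiny_detector(), n_photons = n,
                                seed = 7)$region_mueller)
    abs(M[1, 3])
  }, numeric(1))
  # consistent with ~ n^(-1/2) shrinkage: allow a generous factor
  expect_lt(m13[2], m13[1] * 1.5 + 0.02)
})
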