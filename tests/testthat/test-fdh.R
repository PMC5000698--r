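test_that("FDH of a constant plane puts all mass in one bin with area 1", {
  f <- compute_fdh(matrix(0.25, 10, 10), element = "m22")
  area <- sum(f$density * diff(f$bin_edges))
  expect_equal(area, 1, tolerance = 1e-12)
  expect_equal(sum(f$density > 0), 1)
  mid <- (head(f$bin_edges, -1) + tail(f$bin_edges, -1)) / 2
  expect_lt(abs(mid[which(f$density > 0)] - 0.25), diff(f$bin_edges)[1])
})

test_that("FDH of uniform pixels approaches the flat density", {
  set.seed(8)
  x <- runif(1e6, -1, 1)
  f <- compute_fdh(x, element = "m23", range = c(-1, 1))
  bw <- 2 / 400
  p <- bw / 2               # per-bin probability
  se <- sqrt(p * (1 - p) / 1e6) / bw   # binomial SE on the density scale
  expect_lt(max(abs(f$density - 0.5)), 5 * se)
})

test_that("FDH area is exactly 1 for arbitrary planes, clipping included", {
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(2000, mean = runif(1, -2, 2), sd = runif(1, 0.01, 2))
    f <- compute_fdh(x, element = "m12")
    expect_equal(sum(f$density * diff(f$bin_edges)), 1, tolerance = 1e-9)
  }
  # clipped pixels are counted, not dropped
  f <- compute_fdh(c(-5, 0, 5), n_bins = 10, range = c(-1, 1))
  expect_equal(f$n_clipped, 2L)
  expect_equal(f$n_pixels, 3L)
})

test_that("central moments handle degenerate planes", {
  m <- central_moments(matrix(0.7, 5, 5))
  expect_equal(m$P1, 0.7)
  expect_equal(m$P2, 0)
  expect_true(is.na(m$P3) && is.na(m$P4))

  # symmetric two-point distribution: P4 = 1 (Pearson bound)
  m2 <- central_moments(c(-0.3, 0.3))
  expect_equal(m2$P1, 0)
  expect_equal(m2$P2, 0.09)
  expect_equal(m2$P3, 0)
  expect_equal(m2$P4, 1)
})

test_that("central moments equal brute-force loop sums and Gaussian limits", {
  set.seed(12)
  x <- rnorm(1e5, 0.5, 0.1)
  m <- central_moments(x)
  # loop-sum oracle
  mu <- sum(x) / length(x)
  v <- sum((x - mu)^2) / length(x)
  sk <- sum((x - mu)^3) / length(x) / v^1.5
  ku <- sum((x - mu)^4) / length(x) / v^2
  expect_equal(m$P1, mu, tolerance = 1e-12)
  expect_equal(m$P2, v, tolerance = 1e-12)
  expect_equal(m$P3, sk, tolerance = 1e-12)
  expect_equal(m$P4, ku, tolerance = 1e-12)
  # population limits within 5 standard errors
  n <- 1e5
  expect_lt(abs(m$P1 - 0.5), 5 * 0.1 / sqrt(n))
  expect_lt(abs(m$P2 - 0.01), 5 * sqrt(2 / n) * 0.01)
  expect_lt(abs(m$P3 - 0), 5 * sqrt(6 / n))
  expect_lt(abs(m$P4 - 3), 5 * sqrt(24 / n))
})

test_that("binned and raw moments agree to within one bin width", {
  set.seed(21)
  x <- pmin(1, pmax(-1, rnorm(5e4, 0.3, 0.2)))
  raw <- central_moments(x)
  binned <- fdh_moments(compute_fdh(x, range = c(-1, 1)))
  bw <- 2 / 400
  expect_lt(abs(raw$P1 - binned$P1), bw)
  expect_lt(abs(raw$P2 - binned$P2), bw)
})

test_that("derived parameters follow their definitions on published rows", {
  # wash 0: both d-parameters vanish identically
  F <- load_paper_table("F")
  d0 <- derived_params(F, 0)
  expect_equal(d0$d22p1, 0)
  expect_equal(d0$d23p2, 0)
  # c1p1 from the fabric-softener wash-0 row: (0.536 - 0.039) / 0.536
  expect_equal(d0$c1p1, (0.536 - 0.039) / 0.536, tolerance = 1e-12)
  expect_equal(d0$c1p1, 0.9272, tolerance = 1e-4)
  # toilet soap wash 6 vs 0: m22 P1 0.307 vs 0.560
  T <- load_paper_table("T")
  d6 <- derived_params(T, 6)
  expect_equal(d6$d22p1, (0.307 - 0.560) / 0.560, tolerance = 1e-12)
  expect_equal(d6$d22p1, -0.4518, tolerance = 1e-4)
  expect_lt(d6$d22p1, 0)
})

test_that("derived parameters fail loudly on zero denominators", {
  s <- wash_series(tibble::tibble(
    wash = rep(c(0L, 1L), each = 3),
    element = rep(c("m22", "m33", "m23"), 2),
    P1 = c(0, 0.1, 0.2, 0.5, 0.1, 0.2),
    P2 = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1)))
  expect_error(derived_params(s, 1), "m22")
})

test_that("anisotropy difference reproduces the published narrative values", {
  F <- load_paper_table("F")
  expect_equal(anisotropy_difference(F[F$wash == 0, ]), 0.536 - 0.039)
  T <- load_paper_table("T")
  expect_equal(anisotropy_difference(T[T$wash == 0, ]), 0.560 - 0.039)
  same <- tibble::tibble(element = c("m22", "m33"), P1 = c(0.4, 0.4))
  expect_equal(anisotropy_difference(same), 0)
})

test_that("series report carries fold-changes and P1 shifts per wash", {
  C <- load_paper_table("C")
  rep <- series_report(C)
  expect_equal(nrow(rep), 7)
  # m22 P2 fold change at wash 6: 0.107 / 0.024
  expect_equal(rep$m22_p2_fold[rep$wash == 6], 0.107 / 0.024,
               tolerance = 1e-12)
  expect_gt(rep$m22_p2_fold[rep$wash == 6], 4)
  # m12 P1 maximal change: |0.010 - 0.034|
  expect_equal(max(rep$dP1_m12), 0.024, tolerance = 1e-12)
  expect_gt(max(rep$dP1_m12), 0.02)
})

test_that("a series constant across washes has null derived parameters", {
  base <- tibble::tibble(element = c("m12", "m22", "m23", "m32", "m33"),
                         P1 = c(0.03, 0.5, 0.01, 0.01, 0.04),
                         P2 = c(0.01, 0.02, 0.02, 0.02, 0.02))
  moments <- dplyr::bind_rows(lapply(0:3, function(w) {
    dplyr::mutate(base, wash = w)
  }))
  rep <- series_report(wash_series(moments, "inert"))
  expect_equal(rep$d22p1, rep(0, 4))
  expect_equal(rep$d23p2, rep(0, 4))
  expect_equal(rep$c1p1, rep((0.5 - 0.04) / 0.5, 4))
  expect_equal(max(rep$m22_p2_fold), 1)
})

test_that("rotating an isotropic simulated image leaves element FDHs alike", {
  med <- medium_config(sphere = sphere_species(mus = 80),
                       cylinder = cylinder_species(mus = 1e-9))
  sim <- run_simulation(med, detector_config(grid = c(12L, 12L), extent = 0.5,
                                             acceptance_deg = 20),
                        n_photons = 3e4, seed = 71)
  img <- sim$image
  rot_mask <- t(img$mask)[ncol(img$mask):1, ]   # 90 degree rotation
  for (el in c("m22", "m33")) {
    p <- img$planes[, , el]
    pr <- t(p)[ncol(p):1, ]
    m1 <- central_moments(p, img$mask)
    m2 <- central_moments(pr, rot_mask)
    # identical pixel multiset => rotation alone cannot change moments;
    # this asserts the bookkeeping, sampling error enters only through
    # which pixels are valid (none here)
    expect_equal(m1$P1, m2$P1, tolerance = 1e-12)
    expect_equal(m1$P2, m2$P2, tolerance = 1e-12)
  }
})

test_that("moment recovery on synthetic images hits generator targets", {
  spec <- synthetic_image_spec(
    means = c(m22 = 0.5, m33 = 0.05, m12 = 0.03),
    variances = c(m22 = 0.02, m33 = 0.015, m12 = 0.01),
    size = 316L, seed = 5)      # ~1e5 pixels
  img <- generate_synthetic_image(spec)
  mo <- moment_set(img, elements = c("m12", "m22", "m33"))
  n <- 316^2
  for (el in c("m12", "m22", "m33")) {
    row <- mo[mo$element == el, ]
    expect_lt(abs(row$P1 - spec$means[el]),
              5 * sqrt(spec$variances[el] / n))
    expect_lt(abs(row$P2 - spec$variances[el]),
              5 * sqrt(2 / n) * spec$variances[el])
  }
})
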