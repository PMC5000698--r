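test_that("packaged tables match the published values cell for cell", {
  # spot transcription of the printed central-moment tables
  F <- load_paper_table("F")
  expect_equal(F$P1[F$wash == 0 & F$element == "m22"], 0.536)
  expect_equal(F$P1[F$wash == 0 & F$element == "m12"], 0.030)
  expect_equal(F$P1[F$wash == 6 & F$element == "m32"], -0.030)
  expect_equal(F$P2[F$wash == 3 & F$element == "m23"], 0.020)

  L <- load_paper_table("L")
  expect_equal(L$P1[L$wash == 0 & L$element == "m23"], 0.075)
  expect_equal(L$P1[L$wash == 6 & L$element == "m22"], 0.482)
  expect_equal(L$P2[L$wash == 6 & L$element == "m33"], 0.018)

  T <- load_paper_table("T")
  expect_equal(T$P1[T$wash == 0 & T$element == "m22"], 0.560)
  expect_equal(T$P1[T$wash == 6 & T$element == "m22"], 0.307)
  expect_equal(T$P2[T$wash == 4 & T$element == "m22"], 0.031)

  C <- load_paper_table("C")
  expect_equal(C$P2[C$wash == 6 & C$element == "m22"], 0.107)
  expect_equal(C$P1[C$wash == 6 & C$element == "m33"], 0.182)
  expect_equal(C$P1[C$wash == 1 & C$element == "m23"], 0.134)
  expect_equal(C$P2[C$wash == 0 & C$element == "m22"], 0.024)

  # full first row of the fabric-softener table, verbatim
  r <- F[F$wash == 0, ]
  expect_equal(r$P1[match(c("m12", "m22", "m23", "m32", "m33"), r$element)],
               c(0.030, 0.536, 0.013, 0.008, 0.039))
})

test_that("every packaged series has wash counts 0..6 and five elements", {
  for (d in c("F", "L", "T", "C")) {
    s <- load_paper_table(d)
    expect_equal(sort(unique(s$wash)), 0:6)
    expect_equal(sort(unique(s$element)),
                 c("m12", "m22", "m23", "m32", "m33"))
    expect_false(anyNA(s$P1))
    expect_false(anyNA(s$P2))
  }
})

test_that("synthetic images honour degenerate and deterministic specs", {
  spec0 <- synthetic_image_spec(means = c(m22 = 0.4), size = 16, seed = 2)
  img <- generate_synthetic_image(spec0)
  expect_equal(img$planes[, , "m22"], matrix(0.4, 16, 16))
  expect_equal(img$planes[, , "m11"], matrix(1, 16, 16))
  expect_equal(img$planes[, , "m12"], matrix(0, 16, 16))

  spec1 <- synthetic_image_spec(variances = c(m23 = 0.01), size = 32, seed = 9)
  expect_identical(generate_synthetic_image(spec1)$planes,
                   generate_synthetic_image(spec1)$planes)
  expect_error(synthetic_image_spec(size = 4), "8 x 8")
  expect_error(synthetic_image_spec(variances = c(m22 = -1)), "non-negative")
})

test_that("texture modes shape the planes as documented", {
  stripes <- generate_synthetic_image(synthetic_image_spec(
    means = c(m22 = 0.5, m33 = 0.1), variances = c(m22 = 0.01, m33 = 0.01),
    size = 64, texture = "oriented-stripes", seed = 4))
  # m22 and m33 stripe modulations are anti-correlated by construction
  cc <- cor(as.vector(stripes$planes[, , "m22"]),
            as.vector(stripes$planes[, , "m33"]))
  expect_lt(cc, -0.9)

  smooth <- generate_synthetic_image(synthetic_image_spec(
    variances = c(m12 = 0.01), size = 64, texture = "smooth-field", seed = 4))
  p <- smooth$planes[, , "m12"]
  lag1 <- cor(as.vector(p[, -1]), as.vector(p[, -64]))
  expect_gt(lag1, 0.5)   # spatially correlated, unlike iid noise
})

test_that("wash series assembled from images feed the derived parameters", {
  imgs <- lapply(1:3, function(i) {
    generate_synthetic_image(synthetic_image_spec(
      means = c(m22 = 0.6 - 0.1 * i, m33 = 0.05, m23 = 0.01),
      variances = c(m22 = 0.01, m23 = 0.01 * i), size = 32, seed = i))
  })
  s <- wash_series_from_images(imgs, detergent = "synthetic")
  rep <- series_report(s)
  expect_equal(nrow(rep), 3)
  expect_lt(rep$d22p1[3], 0)        # m22 mean decreases across the series
  expect_gt(rep$d23p2[3], 0)        # m23 variance increases
})

test_that("the end-to-end demo emits trajectories and provenance", {
  out <- withr::local_tempdir()
  res <- end_to_end_demo(n_photons = 800, seed = 3, n_rep = 2,
                         out_dir = out,
                         detector = detector_config(grid = c(8L, 8L),
                                                    extent = 0.5,
                                                    acceptance_deg = 30))
  expect_true(all(c("mode", "step", "c1p1_mean", "d22p1_mean") %in%
                    names(res)))
  expect_equal(nrow(res), 14)
  expect_true(file.exists(file.path(out, "sweep_trajectories.csv")))
  prov <- jsonlite::read_json(file.path(out, "provenance.json"))
  expect_equal(prov$seed, 3)
  expect_equal(prov$n_photons, 800)
})

test_that("the command-line interface runs on toy inputs", {
  cli <- system.file("cli", "silkpol.R", package = "silkpol")
  expect_true(nzchar(cli))
  out_dir <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")

  # tables subcommand: report from a packaged series
  report_csv <- file.path(out_dir, "report.csv")
  st <- system2(rscript, c(cli, "tables", "--detergent", "C",
                           "--out", report_csv), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(report_csv))
  rep <- readr::read_csv(report_csv, show_col_types = FALSE)
  expect_equal(nrow(rep), 7)

  # simulate + analyze on a tiny photon budget
  tif <- file.path(out_dir, "sim.tif")
  system2(rscript, c(cli, "simulate", "--photons", "500", "--seed", "4",
                     "--grid", "8", "--out", tif), stdout = TRUE,
          stderr = TRUE)
  expect_true(file.exists(tif))
  moments_csv <- file.path(out_dir, "moments.csv")
  system2(rscript, c(cli, "analyze", "--image", tif,
                     "--out", moments_csv), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(moments_csv))
  mo <- readr::read_csv(moments_csv, show_col_types = FALSE)
  expect_equal(nrow(mo), 16)

  # reconstruct from a simulated scan written to CSV
  scan_csv <- file.path(out_dir, "scan.csv")
  readr::write_csv(silkpol::simulate_scan(mueller_matrix(diag(4))), scan_csv)
  mm_csv <- file.path(out_dir, "mueller.csv")
  system2(rscript, c(cli, "reconstruct", "--intensities", scan_csv,
                     "--out", mm_csv), stdout = TRUE, stderr = TRUE)
  M <- as.matrix(readr::read_csv(mm_csv, show_col_types = FALSE))
  expect_equal(unname(M), diag(4), tolerance = 1e-8)
})
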