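# Packaged reference tables and synthetic Mueller-image generation.

DETERGENT_FILES <- c(
  F = "table_F_fabric_softener.csv",
  L = "table_L_laundry_powder.csv",
  T = "table_T_toilet_soap.csv",
  C = "table_C_color_stain_net.csv")

DETERGENT_LABELS <- c(
  F = "fabric_softener", L = "laundry_powder",
  T = "toilet_soap", C = "color_stain_net")

#' Load a packaged detergent wash-series table
#'
#' The package ships the published P1/P2 central-moment tables for silk
#' samples washed 0..6 times with four detergents: fabric softener
#' (`"F"`), laundry powder (`"L"`), toilet soap (`"T"`) and color stain
#' net (`"C"`), covering the elements m12, m22, m23, m32 and m33.
#'
#' @param detergent One of `"F"`, `"L"`, `"T"`, `"C"`.
#' @return A [wash_series()] tibble with columns `wash`, `element`,
#'   `P1`, `P2`.
#' @examples
#' s <- load_paper_table("F")
#' anisotropy_difference(s[s$wash == 0, ])  # 0.497
#' @export
load_paper_table <- function(detergent = c("F", "L", "T", "C")) {
  detergent <- match.arg(detergent)
  path <- system.file("extdata", DETERGENT_FILES[[detergent]],
                      package = "silkpol")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged table for detergent ", detergent,
         " is missing; the installation is incomplete")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE)
  long <- tidyr::pivot_longer(raw, cols = -"parameter",
                              names_to = "element", values_to = "value")
  long$moment <- sub("_.*$", "", long$parameter)
  long$wash <- as.integer(sub("^P[12]_", "", long$parameter))
  wide <- tidyr::pivot_wider(long[, c("wash", "element", "moment", "value")],
                             names_from = "moment", values_from = "value")
  wash_series(wide, detergent = DETERGENT_LABELS[[detergent]])
}

#' Specification of a synthetic Mueller image
#'
#' Describes a reproducible test image with controlled per-element pixel
#' statistics. Three spatial texture modes are available:
#' `"iid-gaussian"` (independent pixels), `"smooth-field"` (spatially
#' correlated Gaussian field with the same marginal moments) and
#' `"oriented-stripes"` (sinusoidal modulation of m22/m33 along an axis,
#' mimicking fiber texture).
#'
#' @param means Named numeric vector of target per-element means
#'   (names among m11..m44; unnamed elements default to the identity
#'   pattern: 1 for m11, 0 elsewhere).
#' @param variances Named numeric vector of target per-element pixel
#'   variances (default 0).
#' @param size Image side length in pixels (square image, >= 8).
#' @param texture One of `"iid-gaussian"`, `"smooth-field"`,
#'   `"oriented-stripes"`.
#' @param stripe_axis_deg Stripe orientation for `"oriented-stripes"`.
#' @param seed Integer seed making the image reproducible.
#' @return A list of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(means = c(m11 = 1), variances = numeric(),
                                 size = 64L,
                                 texture = c("iid-gaussian", "smooth-field",
                                             "oriented-stripes"),
                                 stripe_axis_deg = 0, seed = 1L) {
  texture <- match.arg(texture)
  if (size < 8L) stop("image size must be at least 8 x 8")
  if (any(variances < 0)) stop("variances must be non-negative")
  base_mean <- stats::setNames(as.numeric(diag(4)[cbind(
    rep(1:4, each = 4), rep(1:4, 4))]), mueller_elements())
  # identity pattern row-major: diag elements 1
  base_mean[] <- 0
  base_mean[c("m11", "m22", "m33", "m44")] <- 1
  base_mean[names(means)] <- means
  v <- stats::setNames(rep(0, 16), mueller_elements())
  v[names(variances)] <- variances
  structure(list(means = base_mean, variances = v, size = as.integer(size),
                 texture = texture, stripe_axis_deg = stripe_axis_deg,
                 seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

#' Generate a synthetic Mueller image with controlled statistics
#'
#' Produces a seeded, reproducible image whose per-element pixel mean and
#' variance equal the spec targets in expectation. Useful as a test bed
#' for the FDH moment machinery: `central_moments()` on the generated
#' planes recovers the generator parameters within sampling error.
#'
#' @param spec A [synthetic_image_spec()].
#' @return A `mueller_image`.
#' @examples
#' img <- generate_synthetic_image(synthetic_image_spec(
#'   means = c(m22 = 0.5), variances = c(m22 = 0.01), size = 32))
#' @export
generate_synthetic_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  n <- spec$size
  set.seed(spec$seed)
  planes <- array(0, c(n, n, 16L))
  xg <- matrix(rep(seq_len(n), each = n), n, n)         # column index
  yg <- matrix(rep(seq_len(n), times = n), n, n)        # row index
  for (k in 1:16) {
    mu <- spec$means[k]; v <- spec$variances[k]
    if (v == 0) {
      planes[, , k] <- mu
      next
    }
    sdv <- sqrt(v)
    if (spec$texture == "iid-gaussian") {
      planes[, , k] <- mu + matrix(rnorm(n * n, 0, sdv), n, n)
    } else if (spec$texture == "smooth-field") {
      # moving-average smoothing of white noise, rescaled to the target sd
      z <- matrix(rnorm((n + 4) * (n + 4)), n + 4, n + 4)
      sm <- matrix(0, n, n)
      for (di in 0:4) for (dj in 0:4) {
        sm <- sm + z[di + seq_len(n), dj + seq_len(n)]
      }
      sm <- (sm - mean(sm)) / sd(sm)
      planes[, , k] <- mu + sdv * sm
    } else {  # oriented-stripes
      th <- spec$stripe_axis_deg * pi / 180
      phase <- 2 * pi * (xg * cos(th) + yg * sin(th)) / 8
      stripe <- sqrt(2) * sin(phase)   # unit variance, zero mean (approx.)
      stripe <- (stripe - mean(stripe)) / sd(stripe)
      el <- mueller_elements()[k]
      if (el %in% c("m22", "m33")) {
        planes[, , k] <- mu + sdv * stripe * (if (el == "m33") -1 else 1)
      } else {
        planes[, , k] <- mu + matrix(rnorm(n * n, 0, sdv), n, n)
      }
    }
  }
  mueller_image(planes)
}

#' Build a wash series from a list of Mueller images
#'
#' Reduces each image to its per-element central moments and stacks them
#' into a [wash_series()], wash counts taken as 0, 1, ... in list order.
#'
#' @param images List of `mueller_image` objects ordered by wash count.
#' @param detergent Series label.
#' @return A `wash_series`.
#' @export
wash_series_from_images <- function(images, detergent = "simulated") {
  moments <- purrr::imap_dfr(images, function(img, i) {
    m <- moment_set(img)
    m$wash <- as.integer(i - 1L)
    m
  })
  wash_series(moments, detergent = detergent)
}

#' Run both degradation sweeps end to end and report FDH parameters
#'
#' Wires the simulator to the analysis: runs the toilet-soap and
#' color-stain-net degradation sweeps at a stated photon budget,
#' derives c1p1 and d22p1 per sweep step, and (optionally) writes the
#' trajectory table to CSV together with a JSON provenance record
#' (configuration, seeds, runtimes).
#'
#' @param n_photons Photons per input state per replicate.
#' @param seed Base seed.
#' @param n_rep Replicates per step (standard errors come from these).
#' @param out_dir Optional output directory for `sweep_trajectories.csv`
#'   and `provenance.json`.
#' @param base Baseline [medium_config()].
#' @param detector A [detector_config()].
#' @return A tibble: per mode and step, mean and standard error of
#'   `c1p1` and `d22p1`.
#' @export
end_to_end_demo <- function(n_photons = 2e4, seed = 1L, n_rep = 3L,
                            out_dir = NULL, base = medium_config(),
                            detector = detector_config(grid = c(32L, 32L))) {
  t0 <- Sys.time()
  res <- purrr::map_dfr(c("toilet_soap", "color_stain_net"), function(mode) {
    sm <- summarize_sweep(simulate_wash_sweep(
      mode, n_photons = n_photons, seed = seed, n_rep = n_rep,
      base = base, detector = detector))
    sm$mode <- mode
    sm
  })
  res <- res[, c("mode", setdiff(names(res), "mode"))]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(res, file.path(out_dir, "sweep_trajectories.csv"))
    prov <- list(seed = seed, n_photons = n_photons, n_rep = n_rep,
                 medium = unclass(base), detector = unclass(detector),
                 runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                 r_version = as.character(getRversion()))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res
}
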