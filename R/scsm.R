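# Sphere-cylinder scattering-model Monte Carlo: medium/detector
# configuration, the transport driver (C++ kernel), Stokes-basis
# inversion, degradation sweeps and direction-sampling utilities.

#' Spherical scatterer species
#'
#' Small particles attached to fiber surfaces or embedded in the
#' interstitial medium are modeled as homogeneous spheres.
#'
#' @param diameter Sphere diameter in micrometers.
#' @param refractive_index Scatterer refractive index (absolute; divided
#'   by the background index to obtain the relative index).
#' @param mus Scattering coefficient of the sphere population in 1/cm.
#' @return A list of class `sphere_species`.
#' @export
sphere_species <- function(diameter = 0.2, refractive_index = 1.56,
                           mus = 10) {
  stopifnot(diameter > 0, mus >= 0)
  structure(list(diameter = diameter, refractive_index = refractive_index,
                 mus = mus), class = "sphere_species")
}

#' Cylindrical scatterer species
#'
#' Fibers are modeled as infinitely long circular cylinders lying in the
#' sample plane, oriented along the x-axis with a Gaussian angular
#' spread.
#'
#' @param diameter Cylinder diameter in micrometers.
#' @param refractive_index Scatterer refractive index.
#' @param mus Scattering coefficient of the cylinder population in 1/cm.
#' @param orientation_mean In-plane orientation mean in degrees
#'   (0 = x-axis).
#' @param orientation_std Gaussian spread of the orientation in degrees.
#' @return A list of class `cylinder_species`.
#' @export
cylinder_species <- function(diameter = 1.5, refractive_index = 1.56,
                             mus = 70, orientation_mean = 0,
                             orientation_std = 15) {
  stopifnot(diameter > 0, mus >= 0, orientation_std >= 0)
  structure(list(diameter = diameter, refractive_index = refractive_index,
                 mus = mus, orientation_mean = orientation_mean,
                 orientation_std = orientation_std),
            class = "cylinder_species")
}

#' Scattering-medium configuration
#'
#' The slab holding both scatterer species. Defaults describe the silk
#' sample model: a 0.01 cm slab of 1.5 um cylinders along x (15 degree
#' spread) and 0.2 um spheres, indices 1.56 in a background of index 1,
#' at 633 nm.
#'
#' @param thickness Slab thickness in cm.
#' @param sphere A [sphere_species()].
#' @param cylinder A [cylinder_species()].
#' @param background_index Interstitial medium refractive index.
#' @param wavelength Vacuum wavelength in nm.
#' @return A list of class `medium_config`.
#' @export
medium_config <- function(thickness = 0.01, sphere = sphere_species(),
                          cylinder = cylinder_species(),
                          background_index = 1, wavelength = 633) {
  stopifnot(thickness > 0)
  if (sphere$mus + cylinder$mus <= 0) {
    stop("total scattering coefficient must be positive")
  }
  structure(list(thickness = thickness, sphere = sphere,
                 cylinder = cylinder, background_index = background_index,
                 wavelength = wavelength), class = "medium_config")
}

#' Detector configuration for the backscattering image
#'
#' @param grid Length-2 integer (rows, columns) of the pixel grid.
#' @param extent Physical width of the square detection area in cm,
#'   centered on the beam.
#' @param acceptance_deg Half-angle of the detection cone about the
#'   backward normal, degrees; 90 accepts the whole backscattering
#'   hemisphere.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(grid = c(64L, 64L), extent = 0.4,
                            acceptance_deg = 90) {
  stopifnot(all(grid >= 1L), extent > 0,
            acceptance_deg > 0, acceptance_deg <= 90)
  structure(list(grid = as.integer(grid), extent = extent,
                 acceptance_deg = acceptance_deg),
            class = "detector_config")
}

#' Size parameter of a scatterer in the background medium
#'
#' @param diameter Scatterer diameter in micrometers.
#' @param wavelength Vacuum wavelength in nm.
#' @param background_index Background refractive index.
#' @return `pi * d / (lambda / n_bg)`, dimensionless.
#' @export
size_parameter <- function(diameter, wavelength = 633,
                           background_index = 1) {
  pi * diameter * 1000 * background_index / wavelength
}

# phase-table cache: cylinder tables are moderately expensive to build
.silkpol_cache <- new.env(parent = emptyenv())

cached_sphere_table <- function(x, m, n_theta = 721L) {
  key <- sprintf("sph_%.10g_%.10g_%d", x, m, n_theta)
  if (is.null(.silkpol_cache[[key]])) {
    .silkpol_cache[[key]] <- sphere_phase_table(x, m, n_theta)
  }
  .silkpol_cache[[key]]
}

cached_cylinder_table <- function(x, m, n_zeta = 60L, n_theta = 361L) {
  key <- sprintf("cyl_%.10g_%.10g_%d_%d", x, m, n_zeta, n_theta)
  if (is.null(.silkpol_cache[[key]])) {
    .silkpol_cache[[key]] <- cylinder_phase_table(
      x, m, zeta_grid = seq(0.05, pi / 2, length.out = n_zeta),
      n_theta = n_theta)
  }
  .silkpol_cache[[key]]
}

#' The four probing input polarization states
#'
#' Columns are the Stokes vectors of the minimal complete probing basis:
#' horizontal, vertical, +45 degrees linear and right circular.
#'
#' @return A 4x4 matrix (columns H, V, P45, R).
#' @export
input_state_basis <- function() {
  matrix(c(1, 1, 0, 0,
           1, -1, 0, 0,
           1, 0, 1, 0,
           1, 0, 0, 1), 4, 4,
         dimnames = list(c("S0", "S1", "S2", "S3"),
                         c("H", "V", "P45", "R")))
}

#' Recover a Mueller image from output Stokes under a probing basis
#'
#' Per pixel, the Mueller matrix is the linear map taking the four input
#' Stokes vectors to the four accumulated output Stokes vectors:
#' `M = S_out %*% solve(S_in)`. Exact (to rounding) when the outputs
#' were produced by one fixed matrix per pixel.
#'
#' @param out_stokes An `H x W x 4 x 4` array: output Stokes component
#'   (dimension 3) per input state (dimension 4).
#' @param in_basis 4x4 matrix of input Stokes columns; must be
#'   invertible.
#' @param mask Optional logical `H x W` validity mask.
#' @param wavelength Metadata passed to the image.
#' @return An (unnormalized) `mueller_image`.
#' @export
mueller_from_stokes_basis <- function(out_stokes,
                                      in_basis = input_state_basis(),
                                      mask = NULL, wavelength = 633) {
  d <- dim(out_stokes)
  stopifnot(length(d) == 4L, d[3] == 4L, d[4] == ncol(in_basis))
  inv <- tryCatch(solve(in_basis), error = function(e) {
    stop("the input-state basis is singular: probing states must span Stokes space")
  })
  h <- d[1]; w <- d[2]
  planes <- array(0, c(h, w, 16L))
  for (i in 1:4) {
    for (j in 1:4) {
      acc <- matrix(0, h, w)
      for (k in 1:4) acc <- acc + out_stokes[, , i, k] * inv[k, j]
      planes[, , (i - 1) * 4 + j] <- acc
    }
  }
  mueller_image(planes, mask = mask, wavelength = wavelength)
}

#' Run the sphere-cylinder Monte Carlo simulation
#'
#' Launches a pencil beam normally onto the slab for each of the four
#' probing input states (H, V, +45, right circular), transports photons
#' through sphere and cylinder scattering events, bins photons exiting
#' the top surface by exit position, and solves the per-pixel Mueller
#' matrix from the 4-in/4-out Stokes set. The returned image is
#' m11-normalized; pixels never hit in some input state are masked.
#'
#' @param medium A [medium_config()].
#' @param detector A [detector_config()].
#' @param n_photons Photons launched per input state.
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical results.
#' @param redraw_orientation Draw a fresh cylinder orientation at every
#'   scattering event (ensemble average over the angular distribution,
#'   the default) or keep one orientation per photon.
#' @param roulette_wmin,max_scatter Photon termination controls.
#' @return A list of class `scsm_result`: `image` (normalized
#'   `mueller_image`), `counts` (per-pixel detected photons, all
#'   states), `region_mueller` (photon-weighted whole-region normalized
#'   Mueller matrix), `n_detected`, `n_transmitted`, `detected_fraction`
#'   per state, plus the configuration, seed and photon budget.
#' @export
run_simulation <- function(medium, detector = detector_config(),
                           n_photons = 1e5, seed = 1L,
                           redraw_orientation = TRUE,
                           roulette_wmin = 1e-4, max_scatter = 1e5L) {
  stopifnot(inherits(medium, "medium_config"),
            inherits(detector, "detector_config"), n_photons >= 1)
  nbg <- medium$background_index
  xs <- size_parameter(medium$sphere$diameter, medium$wavelength, nbg)
  xc <- size_parameter(medium$cylinder$diameter, medium$wavelength, nbg)
  ms <- medium$sphere$refractive_index / nbg
  mc <- medium$cylinder$refractive_index / nbg
  sph <- cached_sphere_table(xs, ms)
  cyl <- cached_cylinder_table(xc, mc)
  # theta CDF of the unpolarized sphere marginal s11 * sin(theta)
  f <- sph$s11 * sin(sph$theta)
  cdf <- cumsum(c(0, (head(f, -1) + tail(f, -1)) / 2 * diff(sph$theta)))
  cdf <- cdf / cdf[length(cdf)]
  H <- detector$grid[1]; W <- detector$grid[2]
  set.seed(seed)
  res <- run_scsm_mc_cpp(
    as.integer(n_photons), medium$thickness,
    medium$sphere$mus, medium$cylinder$mus,
    medium$cylinder$orientation_mean * pi / 180,
    medium$cylinder$orientation_std * pi / 180,
    redraw_orientation,
    sph$theta, as.matrix(sph[, c("s11", "s12", "s33", "s34")]), cdf,
    cyl$zeta_grid, cyl$theta_grid, as.numeric(cyl$mueller),
    H, W, detector$extent, cos(detector$acceptance_deg * pi / 180),
    input_state_basis(), roulette_wmin, as.integer(max_scatter))
  accum <- array(res$accum, c(H, W, 4L, 4L))
  counts <- array(res$counts, c(H, W, 4L))
  mask <- apply(counts > 0, c(1, 2), all)
  n_det <- res$n_detected
  if (!any(mask)) {
    warning(sprintf(
      "no pixel was hit in all four input states (detected fraction %s); image fully masked",
      paste(sprintf("%.3g", n_det / n_photons), collapse = "/")))
    img <- NULL
  } else {
    img <- mueller_from_stokes_basis(accum, mask = mask,
                                     wavelength = medium$wavelength)
    img <- normalize_by_m11(img, epsilon = 1e-9)
  }
  # photon-weighted whole-region Mueller matrix
  S_out <- apply(accum, c(3, 4), sum)
  region <- if (all(is.finite(S_out)) && sum(n_det) > 0 && S_out[1, 1] > 0) {
    normalize_mueller(mueller_matrix(S_out %*% solve(input_state_basis())))
  } else NULL
  structure(list(image = img, counts = apply(counts, c(1, 2), sum),
                 region_mueller = region,
                 n_detected = n_det, n_transmitted = res$n_transmitted,
                 detected_fraction = n_det / n_photons,
                 medium = medium, detector = detector, seed = seed,
                 n_photons = n_photons,
                 input_basis = input_state_basis()),
            class = "scsm_result")
}

#' @export
print.scsm_result <- function(x, ...) {
  cat(sprintf(
    "SCSM simulation: %g photons/state, seed %d, detected fraction %.3g\n",
    x$n_photons, x$seed, mean(x$detected_fraction)))
  if (!is.null(x$region_mueller)) {
    cat("region-mean normalized Mueller matrix:\n")
    print(round(unclass(x$region_mueller), 4))
  }
  invisible(x)
}

#' Glance at a simulation result
#'
#' @param x An `scsm_result`.
#' @param ... Unused.
#' @return One-row tibble with detection statistics and the region-level
#'   m22, m33, m12 means and the anisotropy ratio
#'   `c1p1 = |m22 - m33| / m22`.
#' @method glance scsm_result
#' @export
glance.scsm_result <- function(x, ...) {
  M <- unclass(x$region_mueller)
  tibble::tibble(n_photons = x$n_photons,
                 detected_fraction = mean(x$detected_fraction),
                 m12 = M[1, 2], m21 = M[2, 1], m22 = M[2, 2],
                 m33 = M[3, 3], m44 = M[4, 4],
                 c1p1 = abs(M[2, 2] - M[3, 3]) / M[2, 2])
}

# --- degradation sweeps ---------------------------------------------------

TOILET_SOAP_RATIOS <- list(c(10, 70), c(13, 67), c(15, 65), c(21, 59),
                           c(22, 58), c(27, 53), c(28, 52))
COLOR_STAIN_STEPS <- list(c(1.5, 15), c(1.0, 15), c(0.9, 19), c(0.86, 19),
                          c(0.76, 20), c(0.68, 21), c(0.68, 22))

#' Medium configuration for one step of a wash-degradation sweep
#'
#' Two degradation modes emulate what the two aggressive detergents do
#' to silk at the wavelength scale:
#' * `"toilet_soap"` — growing surface roughness and particle debris:
#'   the sphere:cylinder scattering-coefficient split moves through
#'   10:70, 13:67, 15:65, 21:59, 22:58, 27:53, 28:52 (1/cm; the total
#'   stays 80/cm, i.e. constant optical thickness).
#' * `"color_stain_net"` — fibers splitting into finer, more disordered
#'   strands: the cylinder diameter and orientation spread move through
#'   (1.5 um, 15 deg), (1.0, 15), (0.9, 19), (0.86, 19), (0.76, 20),
#'   (0.68, 21), (0.68, 22), with the scattering-coefficient split fixed
#'   at the baseline.
#'
#' @param mode `"toilet_soap"` or `"color_stain_net"`.
#' @param step Sweep position 1..7 (1 = unwashed reference state).
#' @param base Baseline [medium_config()].
#' @return The `medium_config` for that sweep position.
#' @examples
#' degradation_sweep("toilet_soap", 1)$sphere$mus  # 10
#' @export
degradation_sweep <- function(mode = c("toilet_soap", "color_stain_net"),
                              step, base = medium_config()) {
  mode <- match.arg(mode)
  if (!(step %in% 1:7)) stop("step must be in 1..7")
  out <- base
  if (mode == "toilet_soap") {
    pair <- TOILET_SOAP_RATIOS[[step]]
    out$sphere$mus <- pair[1]
    out$cylinder$mus <- pair[2]
  } else {
    pair <- COLOR_STAIN_STEPS[[step]]
    out$cylinder$diameter <- pair[1]
    out$cylinder$orientation_std <- pair[2]
  }
  out
}

#' Simulate a full degradation sweep and derive FDH parameters
#'
#' Runs the seven sweep steps with `n_rep` independent replicates each,
#' reduces every run to its region-level Mueller matrix, and derives
#' `c1p1` and `d22p1` (m22 relative to the step-1 reference within each
#' replicate). Replicates give the Monte Carlo standard errors used by
#' the trend checks.
#'
#' @param mode `"toilet_soap"` or `"color_stain_net"`.
#' @param n_photons Photons per input state per replicate.
#' @param seed Base seed; replicate r of step k runs at
#'   `seed + 1000 * r + k`.
#' @param n_rep Number of independent replicates.
#' @param base Baseline [medium_config()].
#' @param detector A [detector_config()].
#' @return A tibble with one row per (step, rep): `step`, `rep`,
#'   `m22`, `m33`, `m12`, `c1p1`, `d22p1`, `detected_fraction`.
#' @export
simulate_wash_sweep <- function(mode, n_photons = 5e4, seed = 1L,
                                n_rep = 3L, base = medium_config(),
                                detector = detector_config(grid = c(32L, 32L),
                                                           extent = 0.4)) {
  runs <- purrr::map_dfr(seq_len(n_rep), function(r) {
    ref_m22 <- NA_real_
    purrr::map_dfr(1:7, function(k) {
      med <- degradation_sweep(mode, k, base)
      sim <- run_simulation(med, detector, n_photons = n_photons,
                            seed = seed + 1000L * r + k)
      M <- unclass(sim$region_mueller)
      row <- tibble::tibble(step = k, rep = r,
                            m12 = M[1, 2], m22 = M[2, 2], m33 = M[3, 3],
                            c1p1 = abs(M[2, 2] - M[3, 3]) / M[2, 2],
                            detected_fraction = mean(sim$detected_fraction))
      if (k == 1L) ref_m22 <<- M[2, 2]
      row$d22p1 <- (M[2, 2] - ref_m22) / ref_m22
      row
    })
  })
  runs
}

#' Summarize a sweep run into per-step means and standard errors
#'
#' @param sweep Output of [simulate_wash_sweep()].
#' @return A tibble per step with mean and standard error of `c1p1` and
#'   `d22p1` across replicates.
#' @export
summarize_sweep <- function(sweep) {
  dplyr::summarise(
    dplyr::group_by(sweep, .data$step),
    c1p1_mean = mean(.data$c1p1),
    c1p1_se = sd(.data$c1p1) / sqrt(dplyr::n()),
    d22p1_mean = mean(.data$d22p1),
    d22p1_se = sd(.data$d22p1) / sqrt(dplyr::n()),
    .groups = "drop")
}

# --- direction sampling (reference R implementation) ----------------------

#' Sample scattering directions from the polarized phase function
#'
#' Reference (R-level) implementation of the importance sampling used
#' inside the transport kernel, exposed for validation: spheres draw the
#' polar angle from the tabulated s11 sin(theta) marginal and the
#' azimuth from the polarization-dependent conditional; cylinders draw
#' the cone azimuth from the tabulated first Mueller row contracted with
#' the incident Stokes. All outgoing cylinder directions satisfy the
#' cone constraint `u_out . axis = u_in . axis` exactly.
#'
#' @param species A [sphere_species()] or [cylinder_species()].
#' @param direction Incoming unit direction (length 3).
#' @param stokes Incident `stokes` vector (in the frame whose parallel
#'   axis is the x-axis projected perpendicular to `direction`).
#' @param n Number of draws.
#' @param wavelength,background_index Optical context.
#' @param phase Optional override of the tabulated phase function: for
#'   spheres a tibble with columns `theta`, `s11`, `s12`, `s33`, `s34`
#'   (e.g. an isotropic test phase function with constant `s11` and zero
#'   polarization coupling).
#' @param axis Cylinder axis (unit, length 3); default drawn per event
#'   from the species orientation distribution (in-plane Gaussian).
#' @return A tibble of sampled events: sphere draws carry `theta`,
#'   `phi`; cylinder draws carry `Theta`, `zeta`; both carry the
#'   outgoing direction `ux`, `uy`, `uz`.
#' @export
sample_scattering_direction <- function(species, direction = c(0, 0, 1),
                                        stokes = silkpol::stokes(1),
                                        n = 1L, wavelength = 633,
                                        background_index = 1,
                                        phase = NULL, axis = NULL) {
  u <- direction / sqrt(sum(direction^2))
  # local frame: m = x-axis projected perp to u (fallback y-axis)
  m <- c(1, 0, 0) - sum(c(1, 0, 0) * u) * u
  if (sqrt(sum(m^2)) < 1e-9) m <- c(0, 1, 0) - sum(c(0, 1, 0) * u) * u
  m <- m / sqrt(sum(m^2))
  nv <- c(u[2] * m[3] - u[3] * m[2], u[3] * m[1] - u[1] * m[3],
          u[1] * m[2] - u[2] * m[1])
  S <- as.numeric(stokes)
  if (inherits(species, "sphere_species")) {
    tab <- if (is.null(phase)) {
      cached_sphere_table(size_parameter(species$diameter, wavelength,
                                         background_index),
                          species$refractive_index / background_index)
    } else phase
    f <- tab$s11 * sin(tab$theta)
    cdf <- cumsum(c(0, (head(f, -1) + tail(f, -1)) / 2 * diff(tab$theta)))
    cdf <- cdf / cdf[length(cdf)]
    th <- stats::approx(cdf, tab$theta, runif(n), ties = "ordered")$y
    r <- stats::approx(tab$theta, ifelse(tab$s11 > 0, tab$s12 / tab$s11, 0),
                       th)$y
    k1 <- r * S[2] / S[1]; k2 <- r * S[3] / S[1]
    phi <- vapply(seq_len(n), function(i) {
      invert_phi_cdf(k1[i], k2[i], runif(1))
    }, numeric(1))
    e1 <- outer(cos(phi), m) + outer(sin(phi), nv)
    un <- outer(cos(th), u) + sin(th) * e1
    tibble::tibble(theta = th, phi = phi,
                   ux = un[, 1], uy = un[, 2], uz = un[, 3])
  } else if (inherits(species, "cylinder_species")) {
    tab <- cached_cylinder_table(
      size_parameter(species$diameter, wavelength, background_index),
      species$refractive_index / background_index)
    draws <- purrr::map_dfr(seq_len(n), function(i) {
      a <- if (is.null(axis)) {
        al <- (species$orientation_mean +
                 species$orientation_std * rnorm(1)) * pi / 180
        c(cos(al), sin(al), 0)
      } else axis / sqrt(sum(axis^2))
      cza <- sum(u * a)
      if (cza < 0) { a <- -a; cza <- -cza }
      zeta <- acos(min(1, cza))
      zeta <- min(max(zeta, tab$zeta_grid[1]), tab$zeta_grid[length(tab$zeta_grid)])
      s <- sqrt(max(1e-12, 1 - cza^2))
      e1 <- u - cza * a; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
              a[1] * e1[2] - a[2] * e1[1])
      iz <- which.min(abs(tab$zeta_grid - zeta))
      wgt <- pmax(0, tab$mueller[iz, , 1] * S[1] + tab$mueller[iz, , 2] * S[2] +
                    tab$mueller[iz, , 3] * S[3] + tab$mueller[iz, , 4] * S[4])
      Theta <- tab$theta_grid[sample.int(length(wgt), 1, prob = wgt)]
      un <- cza * a + s * (cos(Theta) * e1 + sin(Theta) * e2)
      tibble::tibble(Theta = Theta, zeta = zeta,
                     ux = un[1], uy = un[2], uz = un[3])
    })
    draws
  } else {
    stop("species must be a sphere_species or cylinder_species")
  }
}

# Newton/bisection inversion of the azimuth conditional CDF
# F(phi) = [phi + (k1 sin 2phi - k2 (cos 2phi - 1)) / 2] / (2 pi)
invert_phi_cdf <- function(k1, k2, u) {
  target <- u * 2 * pi
  lo <- 0; hi <- 2 * pi
  phi <- target
  for (it in 1:100) {
    fv <- phi + 0.5 * (k1 * sin(2 * phi) - k2 * (cos(2 * phi) - 1)) - target
    if (abs(fv) < 1e-12) break
    if (fv > 0) hi <- phi else lo <- phi
    fp <- 1 + k1 * cos(2 * phi) + k2 * sin(2 * phi)
    cand <- if (fp > 1e-8) phi - fv / fp else lo - 1
    phi <- if (cand > lo && cand < hi) cand else (lo + hi) / 2
    if (hi - lo < 1e-14) break
  }
  phi %% (2 * pi)
}
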