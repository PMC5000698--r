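# Infinite circular cylinder at oblique incidence: partial-wave series
# for the four amplitude functions T1..T4 and the single-scattering
# Mueller matrix on the scattering cone.

besselJp <- function(nu, z) {
  if (nu == 0) -besselJ(z, 1) else (besselJ(z, nu - 1) - besselJ(z, nu + 1)) / 2
}
besselYp <- function(nu, z) {
  if (nu == 0) -besselY(z, 1) else (besselY(z, nu - 1) - besselY(z, nu + 1)) / 2
}

#' Partial-wave coefficients of a tilted infinite cylinder
#'
#' Series coefficients of the scattered field of an infinitely long
#' circular cylinder illuminated at angle `zeta` from its axis
#' (`zeta = pi/2` is normal incidence). Case I is incident polarization
#' parallel to the plane containing the cylinder axis and the incident
#' direction; case II perpendicular. At normal incidence the cross
#' coefficients `a_I` and `b_II` vanish and the two cases decouple.
#'
#' @param x Size parameter `pi d / lambda`, > 0.
#' @param m Real relative refractive index.
#' @param zeta Incidence angle from the cylinder axis, radians, in
#'   (0, pi/2]; a configurable grazing cutoff rejects `zeta` below
#'   `cutoff` where the series degenerates.
#' @param cutoff Grazing-incidence cutoff in radians.
#' @return A list with complex vectors `b1` (`b_nI`, n = 0..N), `a2`
#'   (`a_nII`, n = 0..N), `a1` (`a_nI`, n = 1..N), `b2` (`b_nII`,
#'   n = 1..N) and the truncation order `nmax`.
#' @export
cylinder_coefficients <- function(x, m, zeta, cutoff = 1e-3) {
  if (!(is.finite(x) && x > 0)) stop("size parameter x must be positive")
  if (zeta < cutoff || zeta > pi / 2 + 1e-12) {
    stop("incidence angle zeta must lie in (cutoff, pi/2] radians; ",
         "grazing incidence below ", cutoff, " rad is outside the model")
  }
  nmax <- mie_n_terms(x)
  xi_ <- x * sin(zeta)
  eta <- x * sqrt(m^2 - cos(zeta)^2)
  ns <- 0:nmax
  b1 <- complex(nmax + 1L); a2 <- complex(nmax + 1L)
  a1 <- complex(nmax + 1L); b2 <- complex(nmax + 1L)
  for (k in seq_along(ns)) {
    n <- ns[k]
    Jx <- besselJ(xi_, n);  Jpx <- besselJp(n, xi_)
    Je <- besselJ(eta, n);  Jpe <- besselJp(n, eta)
    Hx <- complex(real = Jx, imaginary = besselY(xi_, n))
    Hpx <- complex(real = Jpx, imaginary = besselYp(n, xi_))
    An <- 1i * xi_ * (xi_ * Jpe * Jx - eta * Je * Jpx)
    Bn <- xi_ * (m^2 * xi_ * Jpe * Jx - eta * Je * Jpx)
    Cn <- n * cos(zeta) * eta * Je * Jx * (xi_^2 / eta^2 - 1)
    Dn <- n * cos(zeta) * eta * Je * Hx * (xi_^2 / eta^2 - 1)
    Vn <- xi_ * (m^2 * xi_ * Jpe * Hx - eta * Je * Hpx)
    Wn <- 1i * xi_ * (eta * Je * Hpx - xi_ * Jpe * Hx)
    den <- Wn * Vn + 1i * Dn^2
    a1[k] <- (Cn * Vn - Bn * Dn) / den
    b1[k] <- (Wn * Bn + 1i * Dn * Cn) / den
    a2[k] <- -(An * Vn - 1i * Cn * Dn) / den
    b2[k] <- -1i * (Cn * Wn + An * Dn) / den
  }
  list(b1 = b1, a2 = a2, a1 = a1[-1], b2 = b2[-1], nmax = nmax)
}

#' Amplitude functions T1..T4 of a tilted infinite cylinder
#'
#' Scattered directions lie on a cone of half-angle `zeta` about the
#' cylinder axis; `Theta` is the azimuth around that cone measured from
#' the forward direction. The amplitude matrix maps
#' `(E_par, E_perp)` incident to `(T1 E_par + T4 E_perp,
#' T3 E_par + T2 E_perp)` scattered, components referred to the planes
#' through the cylinder axis and the respective direction. At normal
#' incidence `T3 = T4 = 0`.
#'
#' @param x Size parameter.
#' @param m Real relative refractive index.
#' @param zeta Incidence angle from the cylinder axis, radians.
#' @param Theta Azimuths around the scattering cone, radians.
#' @param cutoff Grazing cutoff passed to [cylinder_coefficients()].
#' @return A list of class `cylinder_solution` with a tibble
#'   `amplitudes` (`Theta`, complex `T1`..`T4`), the coefficient set,
#'   and the scattering efficiencies `Qsca_I`, `Qsca_II` of the two
#'   incident cases from the series coefficients.
#' @export
cylinder_amplitudes <- function(x, m, zeta,
                                Theta = seq(-pi, pi, length.out = 361L),
                                cutoff = 1e-3) {
  co <- cylinder_coefficients(x, m, zeta, cutoff = cutoff)
  n <- seq_len(co$nmax)
  T1 <- T2 <- T3 <- T4 <- complex(length(Theta))
  for (k in seq_along(Theta)) {
    cn <- cos(n * Theta[k]); sn <- sin(n * Theta[k])
    T1[k] <- co$b1[1] + 2 * sum(co$b1[-1] * cn)
    T2[k] <- co$a2[1] + 2 * sum(co$a2[-1] * cn)
    T3[k] <- -2i * sum(co$a1 * sn)
    T4[k] <- -2i * sum(co$b2 * sn)
  }
  Qsca_I <- (2 / x) * (Mod(co$b1[1])^2 +
                         2 * sum(Mod(co$b1[-1])^2 + Mod(co$a1)^2))
  Qsca_II <- (2 / x) * (Mod(co$a2[1])^2 +
                          2 * sum(Mod(co$a2[-1])^2 + Mod(co$b2)^2))
  structure(list(amplitudes = tibble::tibble(Theta = Theta, T1 = T1, T2 = T2,
                                             T3 = T3, T4 = T4),
                 coefficients = co, Qsca_I = Qsca_I, Qsca_II = Qsca_II,
                 x = x, m = m, zeta = zeta),
            class = "cylinder_solution")
}

#' @export
print.cylinder_solution <- function(x, ...) {
  cat(sprintf("Cylinder solution: x = %.4g, m = %.4g, zeta = %.4g rad, Qsca_I = %.6g\n",
              x$x, x$m, x$zeta, x$Qsca_I))
  invisible(x)
}

#' Tabulated cylinder Mueller matrices over tilt and cone azimuth
#'
#' Evaluates the full 16-element single-scattering Mueller matrix of a
#' tilted cylinder on a (zeta, Theta) grid, the table consumed by the
#' Monte Carlo transport kernel (which interpolates linearly in zeta).
#'
#' @param x Size parameter.
#' @param m Relative refractive index.
#' @param zeta_grid Tilt angles in radians (ascending, within
#'   (cutoff, pi/2]).
#' @param n_theta Number of azimuth nodes on \[-pi, pi\].
#' @return A list with `zeta_grid`, `theta_grid` and `mueller`, an
#'   `n_zeta x n_theta x 16` array in row-major element order.
#' @export
cylinder_phase_table <- function(x, m,
                                 zeta_grid = seq(0.05, pi / 2,
                                                 length.out = 60L),
                                 n_theta = 361L) {
  theta_grid <- seq(-pi, pi, length.out = n_theta)
  M <- array(0, c(length(zeta_grid), n_theta, 16L))
  for (iz in seq_along(zeta_grid)) {
    sol <- cylinder_amplitudes(x, m, zeta_grid[iz], theta_grid)
    a <- sol$amplitudes
    for (k in seq_len(n_theta)) {
      M[iz, k, ] <- as.vector(t(unclass(
        phase_matrix_from_amplitudes(a$T1[k], a$T2[k], a$T4[k], a$T3[k]))))
    }
  }
  list(zeta_grid = zeta_grid, theta_grid = theta_grid, mueller = M,
       x = x, m = m)
}
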