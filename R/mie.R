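# Lorenz-Mie solution for homogeneous spheres with real relative index:
# amplitude functions S1/S2, efficiencies, and the block-diagonal
# single-scattering Mueller (phase) matrix.

mie_n_terms <- function(x) ceiling(x + 4 * x^(1 / 3) + 2)

# Mie coefficients a_n, b_n by the standard stable scheme: downward
# recurrence for the logarithmic derivative D_n(mx), upward recurrence
# for the Riccati-Bessel functions psi_n(x), chi_n(x).
mie_coefficients <- function(x, m) {
  nmax <- mie_n_terms(x)
  mx <- m * x
  nstart <- nmax + 15L
  D <- numeric(nstart + 1L)           # D[n+1] = D_n(mx)
  for (n in nstart:1) {
    D[n] <- n / mx - 1 / (D[n + 1L] + n / mx)
  }
  D <- D[2:(nmax + 1L)]               # D_1 .. D_nmax
  psi <- numeric(nmax + 1L); chi <- numeric(nmax + 1L)
  psi0 <- sin(x); psim1 <- cos(x)     # psi_0, psi_{-1}
  chi0 <- cos(x); chim1 <- -sin(x)    # chi_0, chi_{-1}
  psi_prev2 <- psim1; psi_prev1 <- psi0
  chi_prev2 <- chim1; chi_prev1 <- chi0
  a <- complex(nmax); b <- complex(nmax)
  psi_nm1 <- psi0; chi_nm1 <- chi0
  for (n in seq_len(nmax)) {
    psi_n <- (2 * n - 1) / x * psi_prev1 - psi_prev2
    chi_n <- (2 * n - 1) / x * chi_prev1 - chi_prev2
    xi_n <- complex(real = psi_n, imaginary = -chi_n)
    xi_nm1 <- complex(real = psi_nm1, imaginary = -chi_nm1)
    ta <- D[n] / m + n / x
    tb <- D[n] * m + n / x
    a[n] <- (ta * psi_n - psi_nm1) / (ta * xi_n - xi_nm1)
    b[n] <- (tb * psi_n - psi_nm1) / (tb * xi_n - xi_nm1)
    psi_prev2 <- psi_prev1; psi_prev1 <- psi_n
    chi_prev2 <- chi_prev1; chi_prev1 <- chi_n
    psi_nm1 <- psi_n; chi_nm1 <- chi_n
  }
  list(a = a, b = b, nmax = nmax)
}

# angular functions pi_n(mu), tau_n(mu) for all n up to nmax at one mu
mie_pi_tau <- function(mu, nmax) {
  p <- numeric(nmax); t <- numeric(nmax)
  p[1] <- 1
  t[1] <- mu
  if (nmax >= 2) {
    p[2] <- 3 * mu
    t[2] <- 2 * mu * p[2] - 3
    if (nmax >= 3) {
      for (n in 3:nmax) {
        p[n] <- (2 * n - 1) / (n - 1) * mu * p[n - 1] - n / (n - 1) * p[n - 2]
        t[n] <- n * mu * p[n] - (n + 1) * p[n - 1]
      }
    }
  }
  list(pi = p, tau = t)
}

#' Lorenz-Mie amplitude functions and efficiencies of a sphere
#'
#' Sums the partial-wave series to the standard truncation
#' `x + 4 x^(1/3) + 2` for a homogeneous sphere of size parameter `x`
#' (`x = pi d / lambda` in the background medium) and real relative
#' refractive index. Absorption is not modeled.
#'
#' @param x Size parameter, > 0.
#' @param m Real relative refractive index, > 0.
#' @param theta Polar scattering angles in radians (0 = forward).
#' @return A list of class `mie_solution`: tibble `amplitudes` with
#'   columns `theta`, `S1`, `S2` (complex, perpendicular and parallel
#'   amplitudes), plus `Qsca`, `Qext`, `x`, `m`. For a non-absorbing
#'   sphere `Qsca = Qext`; at `theta = 0`, `S1 = S2`.
#' @examples
#' sol <- mie_amplitudes(0.99, 1.56, seq(0, pi, length.out = 19))
#' sol$Qsca
#' @export
mie_amplitudes <- function(x, m, theta = seq(0, pi, length.out = 181L)) {
  if (!(is.finite(x) && x > 0)) stop("size parameter x must be positive")
  if (!(is.finite(m) && m > 0)) stop("relative index m must be positive")
  co <- mie_coefficients(x, m)
  n <- seq_len(co$nmax)
  wn <- (2 * n + 1) / (n * (n + 1))
  S1 <- complex(length(theta)); S2 <- complex(length(theta))
  for (k in seq_along(theta)) {
    pt <- mie_pi_tau(cos(theta[k]), co$nmax)
    S1[k] <- sum(wn * (co$a * pt$pi + co$b * pt$tau))
    S2[k] <- sum(wn * (co$a * pt$tau + co$b * pt$pi))
  }
  Qsca <- 2 / x^2 * sum((2 * n + 1) * (Mod(co$a)^2 + Mod(co$b)^2))
  Qext <- 2 / x^2 * sum((2 * n + 1) * Re(co$a + co$b))
  structure(list(amplitudes = tibble::tibble(theta = theta, S1 = S1, S2 = S2),
                 Qsca = Qsca, Qext = Qext, x = x, m = m,
                 coefficients = co),
            class = "mie_solution")
}

#' @export
print.mie_solution <- function(x, ...) {
  cat(sprintf("Mie solution: x = %.4g, m = %.4g, Qsca = %.6g, Qext = %.6g\n",
              x$x, x$m, x$Qsca, x$Qext))
  invisible(x)
}

#' Mueller (phase) matrix from scattering amplitudes
#'
#' The standard quadratic map from a 2x2 complex amplitude matrix in the
#' scattering-plane basis (parallel component first) to the 4x4 real
#' Mueller matrix: `M = A (J kron conj(J)) A^-1` with `A` the
#' coherency-to-Stokes map. For a sphere pass `S2` (parallel) and `S1`
#' (perpendicular); the result is block-diagonal with the familiar
#' 4-parameter structure. For a tilted cylinder pass the full `T1..T4`
#' set via `Spar_perp`/`Sperp_par`.
#'
#' @param Spar Parallel-to-parallel amplitude (sphere: S2; cylinder: T1).
#' @param Sperp Perpendicular-to-perpendicular amplitude (sphere: S1;
#'   cylinder: T2).
#' @param Spar_perp Perpendicular-to-parallel cross amplitude
#'   (cylinder: T4; 0 for spheres).
#' @param Sperp_par Parallel-to-perpendicular cross amplitude
#'   (cylinder: T3; 0 for spheres).
#' @return A 4x4 real `mueller` matrix (unnormalized).
#' @export
phase_matrix_from_amplitudes <- function(Spar, Sperp, Spar_perp = 0 + 0i,
                                         Sperp_par = 0 + 0i) {
  stopifnot(all(is.finite(c(Mod(Spar), Mod(Sperp), Mod(Spar_perp),
                            Mod(Sperp_par)))))
  J <- matrix(c(Spar, Sperp_par, Spar_perp, Sperp), 2, 2)
  A <- matrix(c(1, 0, 0, 1,
                1, 0, 0, -1,
                0, 1, 1, 0,
                0, 1i, -1i, 0), 4, 4, byrow = TRUE)
  M <- A %*% (J %x% Conj(J)) %*% solve(A)
  if (max(abs(Im(M))) > 1e-10 * max(abs(Re(M)), 1e-300)) {
    stop("amplitude-to-Mueller map produced a non-real matrix")
  }
  mueller_matrix(Re(M))
}

#' Tabulated sphere phase matrix on a polar-angle grid
#'
#' Evaluates the four independent Mueller elements of the sphere
#' single-scattering matrix (s11, s12, s33, s34) on a polar grid,
#' the table consumed by the Monte Carlo transport kernel.
#'
#' @param x Size parameter.
#' @param m Relative refractive index.
#' @param n_theta Number of polar nodes on \[0, pi\].
#' @return A tibble with columns `theta`, `s11`, `s12`, `s33`, `s34`.
#' @export
sphere_phase_table <- function(x, m, n_theta = 721L) {
  sol <- mie_amplitudes(x, m, seq(0, pi, length.out = n_theta))
  S1 <- sol$amplitudes$S1; S2 <- sol$amplitudes$S2
  tibble::tibble(
    theta = sol$amplitudes$theta,
    s11 = (Mod(S2)^2 + Mod(S1)^2) / 2,
    s12 = (Mod(S2)^2 - Mod(S1)^2) / 2,
    s33 = Re(S2 * Conj(S1)),
    s34 = Im(S2 * Conj(S1)))
}
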