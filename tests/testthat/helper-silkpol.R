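# shared fixtures built in code

# a random physical (positive, bounded) Mueller matrix: convex mixture of
# ideal-element chains plus a partial depolarizer
random_physical_mueller <- function() {
  A <- unclass(mueller_retarder(runif(1, 0, 180), runif(1, 0, 180)) %*%
                 mueller_polarizer(runif(1, 0, 180)))
  B <- unclass(mueller_retarder(runif(1, 0, 180), runif(1, 0, 180)))
  w <- runif(3)
  M <- w[1] * A + w[2] * B + w[3] * diag(c(1, runif(3, -0.5, 0.5)))
  mueller_matrix(M / M[1, 1])
}

random_mueller_image <- function(h = 8, w = 8, positive_m11 = TRUE) {
  planes <- array(runif(h * w * 16, -1, 1), c(h, w, 16))
  if (positive_m11) planes[, , 1] <- runif(h * w, 0.5, 2)
  mueller_image(planes)
}

tiny_detector <- function() detector_config(grid = c(8L, 8L), extent = 0.5,
                                            acceptance_deg = 20)

# oracle: Mie coefficients from half-integer-order Bessel functions,
# independent of the package's recurrence implementation
oracle_mie_qsca <- function(x, m) {
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  sj <- function(n, z) sqrt(pi / (2 * z)) * besselJ(z, n + 0.5)
  sy <- function(n, z) sqrt(pi / (2 * z)) * besselY(z, n + 0.5)
  psi <- function(n, z) z * sj(n, z)
  xi <- function(n, z) complex(real = psi(n, z), imaginary = z * sy(n, z))
  dpsi <- function(n, z) psi(n - 1, z) - n / z * psi(n, z)
  dxi <- function(n, z) xi(n - 1, z) - n / z * xi(n, z)
  n <- 1:nmax
  a <- (m * psi(n, m * x) * dpsi(n, x) - psi(n, x) * dpsi(n, m * x)) /
    (m * psi(n, m * x) * dxi(n, x) - xi(n, x) * dpsi(n, m * x))
  b <- (psi(n, m * x) * dpsi(n, x) - m * psi(n, x) * dpsi(n, m * x)) /
    (psi(n, m * x) * dxi(n, x) - m * xi(n, x) * dpsi(n, m * x))
  2 / x^2 * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
}

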