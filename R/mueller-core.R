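#' @useDynLib silkpol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats rnorm runif sd var coef lm
#' @importFrom utils head tail
NULL

#' Mueller-matrix element labels in row-major order
#'
#' @return Character vector `c("m11", "m12", ..., "m44")`.
#' @export
mueller_elements <- function() {
  paste0("m", as.vector(t(outer(1:4, 1:4, paste0))))
}

#' Construct a Stokes vector
#'
#' A Stokes vector describes the intensity (`S0`) and polarization state
#' (`S1` linear horizontal/vertical, `S2` linear +/-45 degrees, `S3`
#' circular) of a light beam or photon packet.
#'
#' @param S0,S1,S2,S3 Numeric scalars; `S0 >= 0` and
#'   `S0^2 >= S1^2 + S2^2 + S3^2` (equality for fully polarized light).
#' @param tol Relative tolerance on the polarization bound.
#' @return A numeric vector of class `stokes`.
#' @examples
#' stokes(1, 1, 0, 0)  # horizontal linear polarization
#' @export
stokes <- function(S0, S1 = 0, S2 = 0, S3 = 0, tol = 1e-9) {
  s <- c(S0, S1, S2, S3)
  if (!all(is.finite(s))) stop("Stokes components must be finite")
  if (S0 < 0) stop("S0 must be non-negative")
  p2 <- S1^2 + S2^2 + S3^2
  if (p2 > S0^2 * (1 + tol) + tol) {
    stop(sprintf("unphysical Stokes vector: S1^2+S2^2+S3^2 = %g > S0^2 = %g",
                 p2, S0^2))
  }
  structure(s, class = "stokes", names = c("S0", "S1", "S2", "S3"))
}

#' Degree of polarization of a Stokes vector
#'
#' @param s A `stokes` vector (or numeric length-4).
#' @return `sqrt(S1^2 + S2^2 + S3^2) / S0`.
#' @export
stokes_dop <- function(s) {
  unname(sqrt(sum(s[2:4]^2)) / s[1])
}

#' Construct a Mueller matrix
#'
#' @param m A 4x4 numeric matrix, or a length-16 vector in row-major
#'   element order m11, m12, ..., m44.
#' @return A 4x4 matrix of class `mueller`.
#' @examples
#' mueller_matrix(diag(4))
#' @export
mueller_matrix <- function(m) {
  if (is.vector(m) && length(m) == 16L) m <- matrix(m, 4, 4, byrow = TRUE)
  if (!is.matrix(m) || !all(dim(m) == c(4L, 4L))) {
    stop("a Mueller matrix must be 4x4 (or a row-major length-16 vector)")
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(paste0("r", 1:4), paste0("c", 1:4))
  structure(m, class = c("mueller", "matrix"))
}

#' Normalize a Mueller matrix by its m11 element
#'
#' Backscattering Mueller images are conventionally reported with every
#' element divided by m11, so that m11 = 1 and all elements lie in
#' \[-1, 1\] for a physical sample.
#'
#' @param M A 4x4 Mueller matrix.
#' @return The normalized `mueller` matrix.
#' @export
normalize_mueller <- function(M) {
  if (M[1, 1] == 0) stop("cannot normalize: m11 is zero")
  mueller_matrix(unclass(M) / M[1, 1])
}

#' Report physical-validity violations of a Mueller matrix
#'
#' Checks the element bounds that any normalized physical Mueller matrix
#' must satisfy: all entries finite and |m_ij| <= m11. Instrument
#' calibration checks (e.g. measuring air and requiring every element of
#' the recovered matrix to be within 0.01 of the identity) are built on
#' the same element-wise scan.
#'
#' @param M A 4x4 Mueller matrix.
#' @param tol Slack allowed above the |m_ij| <= m11 bound.
#' @return A tibble with columns `element`, `value`, `violation` (the
#'   magnitude by which the bound is exceeded) and `kind`
#'   (`"bound"` or `"non-finite"`). Zero rows for a physical matrix.
#' @examples
#' physical_validity_report(mueller_matrix(diag(4)))  # empty
#' @export
physical_validity_report <- function(M, tol = 1e-6) {
  M <- unclass(M)
  labs <- matrix(mueller_elements(), 4, 4, byrow = TRUE)
  m11 <- M[1, 1]
  rows <- list()
  for (i in 1:4) {
    for (j in 1:4) {
      v <- M[i, j]
      if (!is.finite(v)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          element = labs[i, j], value = v, violation = Inf, kind = "non-finite")
      } else if (abs(v) > m11 + tol) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          element = labs[i, j], value = v,
          violation = abs(v) - m11, kind = "bound")
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(element = character(), value = double(),
                          violation = double(), kind = character()))
  }
  dplyr::bind_rows(rows)
}

# --- Mueller algebra used by the polarimeter and simulator ----------------

#' Mueller matrix of an ideal linear polarizer
#'
#' Uses the convention that an ideal polarizer transmits half of
#' unpolarized incident light.
#'
#' @param angle_deg Transmission-axis angle in degrees from horizontal.
#' @return A 4x4 `mueller` matrix.
#' @export
mueller_polarizer <- function(angle_deg = 0) {
  th <- angle_deg * pi / 180
  c2 <- cos(2 * th); s2 <- sin(2 * th)
  mueller_matrix(0.5 * matrix(c(
    1,       c2,      s2,      0,
    c2,      c2^2,    c2 * s2, 0,
    s2,      c2 * s2, s2^2,    0,
    0,       0,       0,       0), 4, 4, byrow = TRUE))
}

#' Mueller matrix of an ideal linear retarder
#'
#' @param angle_deg Fast-axis angle in degrees from horizontal.
#' @param retardance_deg Retardance in degrees (90 for a quarter-wave plate).
#' @return A 4x4 `mueller` matrix.
#' @export
mueller_retarder <- function(angle_deg = 0, retardance_deg = 90) {
  th <- angle_deg * pi / 180
  d <- retardance_deg * pi / 180
  c2 <- cos(2 * th); s2 <- sin(2 * th)
  cd <- cos(d); sd_ <- sin(d)
  mueller_matrix(matrix(c(
    1, 0, 0, 0,
    0, c2^2 + s2^2 * cd, c2 * s2 * (1 - cd), -s2 * sd_,
    0, c2 * s2 * (1 - cd), s2^2 + c2^2 * cd, c2 * sd_,
    0, s2 * sd_, -c2 * sd_, cd), 4, 4, byrow = TRUE))
}

#' Mueller rotation matrix for a frame rotation of the Stokes basis
#'
#' @param phi_rad Rotation angle in radians (of the reference frame about
#'   the propagation axis).
#' @return A 4x4 rotation `mueller` matrix acting on (S0, S1, S2, S3).
#' @export
mueller_rotator <- function(phi_rad) {
  c2 <- cos(2 * phi_rad); s2 <- sin(2 * phi_rad)
  mueller_matrix(matrix(c(
    1, 0, 0, 0,
    0, c2, s2, 0,
    0, -s2, c2, 0,
    0, 0, 0, 1), 4, 4, byrow = TRUE))
}

#' Rotate a Stokes vector into a new reference frame
#'
#' Rotating the local reference frame by `phi` about the propagation
#' direction transforms (S1, S2) by the 2*phi rotation while S0, S3 and
#' the degree of polarization are unchanged. Used for meridian-plane
#' bookkeeping during photon transport.
#'
#' @param s A `stokes` vector.
#' @param phi_rad Frame rotation angle in radians.
#' @return The rotated `stokes` vector.
#' @export
meridian_rotate <- function(s, phi_rad) {
  v <- as.numeric(mueller_rotator(phi_rad) %*% as.numeric(s))
  structure(v, class = "stokes", names = c("S0", "S1", "S2", "S3"))
}

#' @export
print.mueller <- function(x, ...) {
  cat("Mueller matrix (m11 =", format(x[1, 1]), ")\n")
  print(unclass(x), ...)
  invisible(x)
}
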