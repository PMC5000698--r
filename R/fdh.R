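# Frequency-distribution-histogram statistics of Mueller-element images:
# the statistical core reducing 2D element maps to FDHs, central moments
# P1-P4 and the derived anisotropy/depolarization parameters.

#' Frequency distribution histogram of one Mueller-element plane
#'
#' Reduces the pixel values of one element image to a normalized
#' histogram: the value axis is divided into `n_bins` equal parts
#' (400 by default) and the density is scaled so the area under the
#' curve is exactly 1. Values outside `range` are clipped into the
#' boundary bins (and counted) so that the normalization always holds.
#'
#' @param plane Numeric matrix (one element plane) or vector of pixel
#'   values.
#' @param mask Optional logical matrix of valid pixels.
#' @param element Element label attached to the result, e.g. `"m22"`.
#' @param n_bins Number of bins on the value axis.
#' @param range Length-2 numeric, the value-axis span. Normalized Mueller
#'   elements are bounded by \[-1, 1\], the default; pass e.g.
#'   `c(-0.1, 0.1)` to match the conventional off-diagonal display range.
#' @return An object of class `fdh`: a list with `bin_edges` (length
#'   `n_bins + 1`), `density` (length `n_bins`, area 1), `element`,
#'   `n_pixels` and `n_clipped`.
#' @examples
#' f <- compute_fdh(matrix(rnorm(1e4, 0.5, 0.1), 100), element = "m22")
#' sum(f$density * diff(f$bin_edges))  # 1
#' @export
compute_fdh <- function(plane, mask = NULL, element = "m11",
                        n_bins = 400L, range = c(-1, 1)) {
  x <- if (is.null(mask)) as.numeric(plane) else as.numeric(plane[mask])
  x <- x[is.finite(x)]
  if (length(x) < 1L) stop("compute_fdh: no valid pixels")
  lo <- range[1]; hi <- range[2]
  if (!(lo < hi)) stop("range must satisfy lo < hi")
  n_clipped <- sum(x < lo | x > hi)
  x <- pmin(pmax(x, lo), hi)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bw <- (hi - lo) / n_bins
  # right-closed bins, with the minimum included in bin 1
  idx <- pmin(pmax(ceiling((x - lo) / bw), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  density <- counts / (length(x) * bw)
  structure(list(bin_edges = edges, density = density, element = element,
                 n_pixels = length(x), n_clipped = n_clipped),
            class = "fdh")
}

#' @export
print.fdh <- function(x, ...) {
  cat(sprintf("FDH of %s: %d bins on [%g, %g], %d pixels (%d clipped)\n",
              x$element, length(x$density), min(x$bin_edges),
              max(x$bin_edges), x$n_pixels, x$n_clipped))
  invisible(x)
}

#' @method tidy fdh
#' @export
tidy.fdh <- function(x, ...) {
  mid <- (head(x$bin_edges, -1) + tail(x$bin_edges, -1)) / 2
  tibble::tibble(element = x$element, midpoint = mid, density = x$density)
}

#' @method autoplot fdh
#' @export
autoplot.fdh <- function(object, ...) {
  ggplot2::ggplot(tidy.fdh(object),
                  ggplot2::aes(x = .data$midpoint, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = object$element, y = "density")
}

#' Approximate moments of a histogram
#'
#' Mean and variance of an [compute_fdh()] histogram computed from bin
#' midpoints. Used to check binning bias against the raw-pixel moments:
#' the two agree to within one bin width.
#'
#' @param fdh An `fdh` object.
#' @return A tibble with `P1` and `P2`.
#' @export
fdh_moments <- function(fdh) {
  mid <- (head(fdh$bin_edges, -1) + tail(fdh$bin_edges, -1)) / 2
  w <- fdh$density * diff(fdh$bin_edges)
  m <- sum(w * mid)
  tibble::tibble(P1 = m, P2 = sum(w * (mid - m)^2))
}

#' Central moments P1-P4 of an element plane
#'
#' The four central-moment statistics of the pixel-value distribution:
#' mean (P1), variance (P2, population denominator n), skewness
#' (P3 = E(X-mu)^3 / sigma^3) and non-excess kurtosis
#' (P4 = E(X-mu)^4 / sigma^4, Gaussian -> 3). Moments are taken on the
#' raw pixel values, not the binned histogram, so the derived parameters
#' carry no binning bias.
#'
#' @param plane Numeric matrix or vector of pixel values.
#' @param mask Optional logical matrix of valid pixels.
#' @param element Optional element label carried into the result.
#' @return A one-row tibble with columns `element`, `P1`, `P2`, `P3`,
#'   `P4`, `n_pixels`. When the variance is zero P3 and P4 are `NA`
#'   (undefined), not numbers.
#' @examples
#' central_moments(c(-1, 1))  # P1 = 0, P2 = 1, P3 = 0, P4 = 1
#' @export
central_moments <- function(plane, mask = NULL, element = NA_character_) {
  x <- if (is.null(mask)) as.numeric(plane) else as.numeric(plane[mask])
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 1L) stop("central_moments: no valid pixels")
  mu <- mean(x)
  v <- mean((x - mu)^2)
  if (n >= 2L && v > 0) {
    s <- sqrt(v)
    P3 <- mean((x - mu)^3) / s^3
    P4 <- mean((x - mu)^4) / s^4
  } else {
    P3 <- NA_real_; P4 <- NA_real_
  }
  tibble::tibble(element = element, P1 = mu, P2 = v, P3 = P3, P4 = P4,
                 n_pixels = n)
}

#' Central moments of every element of a Mueller image
#'
#' @param img A `mueller_image` (normally m11-normalized).
#' @param elements Which element planes to reduce (all 16 by default).
#' @return A tibble with one row per element: `element`, `P1`..`P4`,
#'   `n_pixels`.
#' @export
moment_set <- function(img, elements = mueller_elements()) {
  stopifnot(inherits(img, "mueller_image"))
  purrr::map_dfr(elements, function(el) {
    central_moments(img$planes[, , el], mask = img$mask, element = el)
  })
}

#' Signed m22 - m33 anisotropy difference
#'
#' The difference between the mean values (P1) of the m22 and m33
#' element distributions: the larger this difference, the more prominent
#' the anisotropy of the fibrous sample.
#'
#' @param moments A moment table with columns `element` and `P1`
#'   containing rows for `m22` and `m33` (e.g. one wash count of a
#'   [wash_series()], or the output of [moment_set()]).
#' @return The signed scalar `P1(m22) - P1(m33)`.
#' @examples
#' anisotropy_difference(tibble::tibble(element = c("m22", "m33"),
#'                                      P1 = c(0.536, 0.039)))  # 0.497
#' @export
anisotropy_difference <- function(moments) {
  p1 <- function(el) {
    r <- moments$P1[moments$element == el]
    if (length(r) != 1L || is.na(r)) stop("P1 undefined for ", el)
    r
  }
  p1("m22") - p1("m33")
}

# --- wash series ----------------------------------------------------------

#' Assemble a wash series of moment tables
#'
#' A wash series holds the per-element central moments of one sample
#' followed over consecutive washes with one detergent: the tabular form
#' behind the reported moment tables and the derived-parameter
#' trajectories.
#'
#' @param moments A tibble with columns `wash` (integer counts starting
#'   at 0, strictly increasing), `element`, `P1`, `P2` (optionally `P3`,
#'   `P4`), e.g. stacked [moment_set()] outputs.
#' @param detergent Label of the detergent (`"fabric_softener"`, ...).
#' @return The input tibble with class `wash_series` and a `detergent`
#'   attribute.
#' @export
wash_series <- function(moments, detergent = "unknown") {
  stopifnot(is.data.frame(moments),
            all(c("wash", "element", "P1", "P2") %in% names(moments)))
  w <- sort(unique(moments$wash))
  if (w[1] != 0L) stop("a wash series must contain the unwashed state (wash 0)")
  out <- tibble::as_tibble(moments)
  out <- out[order(out$wash, out$element), ]
  class(out) <- c("wash_series", class(out))
  attr(out, "detergent") <- detergent
  out
}

series_moment <- function(series, wash, element, what = c("P1", "P2")) {
  what <- match.arg(what)
  r <- series[[what]][series$wash == wash & series$element == element]
  if (length(r) != 1L || is.na(r)) {
    stop(sprintf("%s of %s undefined at wash %d", what, element, wash))
  }
  r
}

#' Derived FDH parameters c1_p1, d22_p1 and d23_p2 at one wash count
#'
#' Three scalar indicators built from the P1/P2 central moments:
#' * `c1p1 = |P1(m22) - P1(m33)| / P1(m22)` at wash `i` — the anisotropy
#'   degree of the fibrous sample;
#' * `d22p1 = (P1_i(m22) - P1_0(m22)) / P1_0(m22)` — relative shift of
#'   the m22 mean against the unwashed state, negatively related to the
#'   depolarization ability;
#' * `d23p2 = (P2_i(m23) - P2_0(m23)) / P2_0(m23)` — relative change of
#'   the m23 distribution width, related to the degree of order.
#'
#' Both d-parameters are exactly 0 at wash 0 by definition.
#'
#' @param series A [wash_series()].
#' @param wash Wash count `i` (must be present in the series, as must
#'   wash 0).
#' @return A one-row tibble: `wash`, `c1p1`, `d22p1`, `d23p2`.
#' @export
derived_params <- function(series, wash) {
  if (!wash %in% series$wash) stop("wash count ", wash, " not in series")
  m22_i <- series_moment(series, wash, "m22", "P1")
  m33_i <- series_moment(series, wash, "m33", "P1")
  m22_0 <- series_moment(series, 0L, "m22", "P1")
  m23_0 <- series_moment(series, 0L, "m23", "P2")
  m23_i <- series_moment(series, wash, "m23", "P2")
  if (m22_i == 0) stop("undefined parameter c1p1: P1 of m22 is zero at wash ", wash)
  if (m22_0 == 0) stop("undefined parameter d22p1: P1 of m22 is zero at wash 0")
  if (m23_0 == 0) stop("undefined parameter d23p2: P2 of m23 is zero at wash 0")
  tibble::tibble(
    wash = wash,
    c1p1 = abs(m22_i - m33_i) / m22_i,
    d22p1 = (m22_i - m22_0) / m22_0,
    d23p2 = (m23_i - m23_0) / m23_0)
}

#' Per-wash report of derived parameters and table-level readouts
#'
#' One row per wash count of a series, assembling the three derived
#' parameters, the signed m22 - m33 anisotropy difference, the
#' fold-change of the m22 variance against the unwashed state, and the
#' absolute P1 change of every element against the unwashed state
#' (columns `dP1_<element>`).
#'
#' @param series A [wash_series()].
#' @return A tibble with one row per wash count.
#' @examples
#' \dontrun{
#' series_report(load_paper_table("C"))
#' }
#' @export
series_report <- function(series) {
  washes <- sort(unique(series$wash))
  els <- sort(unique(series$element))
  purrr::map_dfr(washes, function(w) {
    dp <- derived_params(series, w)
    sub <- series[series$wash == w, ]
    dp$aniso_diff <- anisotropy_difference(sub)
    dp$m22_p2_fold <- series_moment(series, w, "m22", "P2") /
      series_moment(series, 0L, "m22", "P2")
    for (el in els) {
      dp[[paste0("dP1_", el)]] <-
        abs(series_moment(series, w, el, "P1") -
              series_moment(series, 0L, el, "P1"))
    }
    dp
  })
}

#' @method tidy wash_series
#' @export
tidy.wash_series <- function(x, ...) {
  out <- tibble::as_tibble(x)
  tidyr::pivot_longer(out, cols = dplyr::any_of(c("P1", "P2", "P3", "P4")),
                      names_to = "moment", values_to = "value")
}

#' One-row summary of a wash series
#'
#' @param x A `wash_series`.
#' @param ... Unused.
#' @return A tibble with the detergent label, number of washes, the
#'   wash-0 and final anisotropy differences, the final derived
#'   parameters and the maximal m22 P2 fold-change.
#' @method glance wash_series
#' @export
glance.wash_series <- function(x, ...) {
  rep <- series_report(x)
  last <- rep[which.max(rep$wash), ]
  tibble::tibble(
    detergent = attr(x, "detergent"),
    n_washes = max(rep$wash),
    aniso_diff_0 = rep$aniso_diff[rep$wash == 0],
    aniso_diff_final = last$aniso_diff,
    c1p1_final = last$c1p1,
    d22p1_final = last$d22p1,
    d23p2_final = last$d23p2,
    max_m22_p2_fold = max(rep$m22_p2_fold))
}

#' Plot derived-parameter trajectories of one or more wash series
#'
#' @param object A `wash_series` (or a list of them).
#' @param ... Further `wash_series` objects to overlay.
#' @return A `ggplot` of c1p1, d22p1 and d23p2 against wash count.
#' @method autoplot wash_series
#' @export
autoplot.wash_series <- function(object, ...) {
  all <- c(list(object), Filter(function(o) inherits(o, "wash_series"),
                                list(...)))
  df <- purrr::map_dfr(all, function(s) {
    r <- series_report(s)
    r$detergent <- attr(s, "detergent")
    r
  })
  long <- tidyr::pivot_longer(
    df[, c("wash", "detergent", "c1p1", "d22p1", "d23p2")],
    cols = c("c1p1", "d22p1", "d23p2"),
    names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$wash, y = .data$value,
                                     color = .data$detergent)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "wash count", y = NULL)
}
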