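#' Construct a Mueller-matrix image
#'
#' The central container passed between the simulator, the polarimeter and
#' the FDH analysis: 16 co-registered scalar planes, one per Mueller
#' element m11..m44 (row-major), plus a logical mask of valid pixels.
#'
#' Coordinate convention: image row 1 is the top of the field of view and
#' the x-axis (fiber direction 0 degrees) is the horizontal image axis.
#'
#' @param planes An `H x W x 16` numeric array (third dimension in element
#'   order m11, m12, ..., m44), or a named list of 16 `H x W` matrices.
#' @param mask Logical `H x W` matrix of valid pixels; default all `TRUE`.
#' @param wavelength Illumination wavelength in nm (metadata).
#' @param pixel_pitch Physical size of one pixel (cm), optional metadata.
#' @return An object of class `mueller_image`.
#' @examples
#' img <- mueller_image(array(rep(diag(4), each = 4), c(2, 2, 16)))
#' @export
mueller_image <- function(planes, mask = NULL, wavelength = 633,
                          pixel_pitch = NULL) {
  if (is.list(planes)) {
    stopifnot(length(planes) == 16L)
    planes <- array(unlist(planes, use.names = FALSE),
                    c(dim(planes[[1]]), 16L))
  }
  if (!(is.array(planes) && length(dim(planes)) == 3L && dim(planes)[3] == 16L)) {
    stop("planes must be an H x W x 16 array or a list of 16 matrices")
  }
  h <- dim(planes)[1]; w <- dim(planes)[2]
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  if (!identical(dim(mask), c(h, w))) stop("mask shape must match the planes")
  dimnames(planes) <- list(NULL, NULL, mueller_elements())
  structure(list(planes = planes, mask = mask > 0,
                 wavelength = wavelength, pixel_pitch = pixel_pitch),
            class = "mueller_image")
}

#' @export
print.mueller_image <- function(x, ...) {
  d <- dim(x$planes)
  cat(sprintf("Mueller image: %d x %d pixels, %d valid (%.1f%%), lambda = %s nm\n",
              d[1], d[2], sum(x$mask), 100 * mean(x$mask),
              format(x$wavelength)))
  invisible(x)
}

#' Extract one element plane of a Mueller image
#'
#' @param img A `mueller_image`.
#' @param element Element label, e.g. `"m22"`.
#' @return The `H x W` numeric matrix of that element.
#' @export
mueller_plane <- function(img, element) {
  element <- match.arg(element, mueller_elements())
  img$planes[, , element]
}

#' Normalize a Mueller image by its m11 plane
#'
#' Divides every plane pixel-wise by m11, the convention under which all
#' elements of a physical sample lie in \[-1, 1\] and the m11 plane is
#' identically 1. Pixels where m11 falls below `epsilon` times the m11
#' maximum (dark borders outside the illuminated spot) are removed from
#' the mask instead of producing infinities.
#'
#' @param img A `mueller_image`.
#' @param epsilon Relative threshold on m11 (fraction of the m11 plane
#'   maximum) below which a pixel is masked out.
#' @return The normalized `mueller_image`. Idempotent on valid pixels.
#' @export
normalize_by_m11 <- function(img, epsilon = 1e-6) {
  stopifnot(inherits(img, "mueller_image"), epsilon > 0)
  m11 <- img$planes[, , 1]
  if (!all(is.finite(m11[img$mask]))) stop("m11 plane contains non-finite values")
  cut <- epsilon * max(m11[img$mask], 0)
  mask <- img$mask & is.finite(m11) & (m11 > cut)
  if (!any(mask)) stop("normalize_by_m11: no valid pixels remain (empty mask)")
  planes <- img$planes
  safe <- ifelse(mask, m11, 1)
  for (k in 16:1) planes[, , k] <- planes[, , k] / safe
  planes[, , 1][mask] <- 1  # exact, also under re-application
  out <- img
  out$planes <- planes
  out$mask <- mask
  out
}

# --- raster I/O -----------------------------------------------------------

sidecar_path <- function(path) paste0(path, ".json")

#' Write a Mueller image to disk
#'
#' Two layouts are supported: `"multi-page"` (a 16-page TIFF, one page per
#' element in row-major order m11..m44) and `"4x4-mosaic"` (a single page
#' tiling the 16 planes row-major into a 4x4 grid; TIFF or PNG by file
#' extension). Sample values are affine-mapped onto \[0, 1\] for storage;
#' the scale and offset, the mask and the metadata are written to a JSON
#' sidecar `<path>.json` so that reading restores the original values
#' (to a few 1e-9 absolute for data in \[-1, 1\] at the default 32-bit
#' depth; bit-exact for integer-valued rasters via `bits = 16`).
#'
#' @param img A `mueller_image`.
#' @param path Output file path (`.tif`/`.tiff`, or `.png` for mosaics).
#' @param layout `"multi-page"` or `"4x4-mosaic"`.
#' @param bits Bits per stored sample (32 or 16; PNG mosaics use 16).
#' @return `path`, invisibly.
#' @export
write_mueller_image <- function(img, path,
                                layout = c("multi-page", "4x4-mosaic"),
                                bits = 32L) {
  stopifnot(inherits(img, "mueller_image"))
  layout <- match.arg(layout)
  is_png <- grepl("\\.png$", path, ignore.case = TRUE)
  if (is_png && layout != "4x4-mosaic") {
    stop("PNG output supports only the 4x4-mosaic layout")
  }
  vals <- img$planes
  lo <- min(vals); hi <- max(vals)
  scale <- if (hi > lo) hi - lo else 1
  stored <- (vals - lo) / scale
  meta <- list(format = "silkpol-mueller-image", layout = layout,
               height = dim(vals)[1], width = dim(vals)[2],
               element_order = mueller_elements(),
               offset = lo, scale = scale, bits = as.integer(bits),
               wavelength = img$wavelength,
               pixel_pitch = img$pixel_pitch,
               mask_packed = paste(as.integer(t(img$mask)), collapse = ""))
  if (layout == "multi-page") {
    pages <- lapply(1:16, function(k) stored[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                    compression = "none", reduce = FALSE)
  } else {
    h <- dim(vals)[1]; w <- dim(vals)[2]
    mos <- matrix(0, 4 * h, 4 * w)
    for (i in 1:4) for (j in 1:4) {
      mos[(i - 1) * h + 1:h, (j - 1) * w + 1:w] <- stored[, , (i - 1) * 4 + j]
    }
    if (is_png) {
      png::writePNG(mos, path, bits = 16L)
      meta$bits <- 16L
    } else {
      tiff::writeTIFF(mos, path, bits.per.sample = as.integer(bits),
                      compression = "none", reduce = FALSE)
    }
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a Mueller image from disk
#'
#' Counterpart of [write_mueller_image()]. If the JSON sidecar written
#' alongside the raster is present it supplies the layout, value scaling,
#' mask and metadata; without a sidecar the raw stored values in \[0, 1\]
#' are returned with a full mask.
#'
#' @param path Raster file path.
#' @param layout `"multi-page"` or `"4x4-mosaic"`; overridden by the
#'   sidecar when one exists.
#' @return A `mueller_image`.
#' @export
read_mueller_image <- function(path, layout = c("multi-page", "4x4-mosaic")) {
  layout <- match.arg(layout)
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    layout <- meta$layout
  }
  is_png <- grepl("\\.png$", path, ignore.case = TRUE)
  if (layout == "multi-page") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != 16L) {
      stop(sprintf(paste0("expected a 16-page file under the multi-page ",
                          "layout (m11..m44, row-major); found %d pages"),
                   length(pages)))
    }
    pages <- lapply(pages, collapse_gray)
    stored <- array(unlist(pages), c(dim(pages[[1]]), 16L))
  } else {
    mos <- if (is_png) png::readPNG(path) else tiff::readTIFF(path)
    mos <- collapse_gray(mos)
    if (any(dim(mos) %% 4 != 0)) {
      stop("expected a 4x4-mosaic layout: image dimensions must be multiples of 4")
    }
    h <- nrow(mos) / 4; w <- ncol(mos) / 4
    stored <- array(0, c(h, w, 16L))
    for (i in 1:4) for (j in 1:4) {
      stored[, , (i - 1) * 4 + j] <- mos[(i - 1) * h + 1:h, (j - 1) * w + 1:w]
    }
  }
  mask <- NULL
  wavelength <- 633; pitch <- NULL
  if (!is.null(meta)) {
    stored <- stored * meta$scale + meta$offset
    bitsv <- strtoi(strsplit(meta$mask_packed, "")[[1]])
    mask <- matrix(as.logical(bitsv), meta$height, meta$width, byrow = TRUE)
    wavelength <- meta$wavelength
    if (!is.null(meta$pixel_pitch)) pitch <- meta$pixel_pitch
  }
  mueller_image(stored, mask = mask, wavelength = wavelength,
                pixel_pitch = pitch)
}

# readTIFF/readPNG may return H x W x channels; keep the first channel
collapse_gray <- function(x) {
  if (length(dim(x)) == 3L) x[, , 1] else x
}

#' Region-mean Mueller matrix of an image
#'
#' Averages each element plane over the valid pixels of `img` (optionally
#' restricted to a centered square subregion), the region-level readout
#' used when comparing simulated images against table statistics.
#'
#' @param img A `mueller_image`.
#' @param fraction Side fraction of a centered square subregion (1 = whole
#'   image).
#' @return A 4x4 `mueller` matrix of region means.
#' @export
region_mean_mueller <- function(img, fraction = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  h <- dim(img$planes)[1]; w <- dim(img$planes)[2]
  ri <- seq.int(max(1, floor(h * (1 - fraction) / 2) + 1),
                min(h, ceiling(h * (1 + fraction) / 2)))
  ci <- seq.int(max(1, floor(w * (1 - fraction) / 2) + 1),
                min(w, ceiling(w * (1 + fraction) / 2)))
  sel <- img$mask[ri, ci, drop = FALSE]
  if (!any(sel)) stop("no valid pixels in the requested region")
  m <- vapply(1:16, function(k) {
    mean(img$planes[ri, ci, k][sel])
  }, numeric(1))
  mueller_matrix(m)
}

#' Plot a Mueller image as a 4x4 panel of element maps
#'
#' @param object A `mueller_image`.
#' @param diag_limits,offdiag_limits Color limits for the diagonal
#'   (m11, m22, m33, m44) and off-diagonal panels; the conventional
#'   display uses \[-1, 1\] and \[-0.1, 0.1\].
#' @param ... Unused.
#' @return A `ggplot` object.
#' @method autoplot mueller_image
#' @export
autoplot.mueller_image <- function(object, diag_limits = c(-1, 1),
                                   offdiag_limits = c(-0.1, 0.1), ...) {
  df <- tidy.mueller_image(object)
  diag_el <- c("m11", "m22", "m33", "m44")
  df$value_scaled <- ifelse(df$element %in% diag_el,
                            pmax(-1, pmin(1, df$value / max(abs(diag_limits)))),
                            pmax(-1, pmin(1, df$value / max(abs(offdiag_limits)))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value_scaled)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~element, nrow = 4) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), name = "scaled value") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Tidy a Mueller image into a long tibble of pixel values
#'
#' @param x A `mueller_image`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `element`, `value`,
#'   restricted to valid pixels.
#' @method tidy mueller_image
#' @export
tidy.mueller_image <- function(x, ...) {
  h <- dim(x$planes)[1]; w <- dim(x$planes)[2]
  idx <- which(x$mask, arr.ind = TRUE)
  purrr::map_dfr(mueller_elements(), function(el) {
    tibble::tibble(row = idx[, 1], col = idx[, 2], element = el,
                   value = x$planes[, , el][x$mask])
  })
}
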