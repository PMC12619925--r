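#' Read an 8-bit raster image
#'
#' Decodes a PNG, TIFF or JPEG photograph into the integer raster the
#' pipeline consumes: a `height x width` matrix (grayscale) or
#' `height x width x 3` array (RGB) of intensities 0-255, row-major with the
#' origin at the top-left and y increasing downward.  An alpha channel, if
#' present, is stripped; transparency plays no role in the protocol.  Only
#' 8-bit inputs are accepted: 16-bit or float images are rejected with an
#' error rather than silently rescaled.  JPEG is accepted as decoded; note
#' that lossy compression perturbs histograms and hence entropy.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return An integer matrix or `h x w x 3` array of 0-255 intensities.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Image file not found: '%s'.", path),
          class = "chromentropy_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    abort(sprintf("Unsupported image format '.%s' (need PNG, TIFF or JPEG).",
                  ext), class = "chromentropy_io_error")
  )
  # Decoders return intensities scaled to [0, 1]; an 8-bit source maps back
  # onto exact multiples of 1/255.  Anything off that grid is a deeper bit
  # depth, which the 0-255 protocol does not cover.
  scaled <- img * 255
  if (max(abs(scaled - round(scaled))) > 1e-6) {
    abort(sprintf("'%s' is not an 8-bit image; only 0-255 inputs are supported.",
                  path), class = "chromentropy_unsupported_image")
  }
  validate_raster(round(scaled))
}

# Normalizes anything image-like into the internal integer raster form and
# enforces the 8-bit contract.  Strips alpha (2- or 4-channel inputs).
validate_raster <- function(image) {
  if (is.matrix(image)) {
    vals <- image
  } else if (is.array(image) && length(dim(image)) == 3L) {
    ch <- dim(image)[3]
    if (ch == 2L) image <- image[, , 1, drop = FALSE]        # gray + alpha
    if (ch == 4L) image <- image[, , 1:3, drop = FALSE]      # RGB + alpha
    ch <- dim(image)[3]
    if (ch == 1L) {
      vals <- array(image, dim(image)[1:2])
    } else if (ch == 3L) {
      vals <- image
    } else {
      abort(sprintf("Unsupported image: %d channels (need 1 or 3).", ch),
            class = "chromentropy_unsupported_image")
    }
  } else {
    abort("Image must be a matrix (grayscale) or h x w x 3 array (RGB).",
          class = "chromentropy_unsupported_image")
  }
  if (anyNA(vals) || min(vals) < 0 || max(vals) > 255 ||
      any(vals != trunc(vals))) {
    abort("Image values must be integers in [0, 255] (8-bit).",
          class = "chromentropy_unsupported_image")
  }
  storage.mode(vals) <- "integer"
  vals
}

# ImageJ-style rounding: int(x + 0.5) on non-negative values, i.e. half away
# from zero, unlike R's banker's round().
round_half_up <- function(x) floor(x + 0.5)

#' Convert an RGB image to 8-bit grayscale
#'
#' Two conventions are offered, both recorded in provenance since entropy is
#' only comparable within one convention:
#' * `"unweighted_mean"` — `round((r + g + b) / 3)`, the plain RGB average
#'   (ImageJ's default conversion with channel weighting off).
#' * `"luma_bt601"` — `round(0.299 r + 0.587 g + 0.114 b)`, the perceptual
#'   luma standard.
#'
#' Rounding is half away from zero, matching ImageJ's `int(x + 0.5)`.  A
#' 1-channel input is returned unchanged under either method.
#'
#' @param image An RGB array or grayscale matrix of 0-255 integers (see
#'   [read_raster()]).
#' @param method Grayscale conversion method.
#' @return An integer matrix with attribute `grayscale_method`.
#' @export
to_grayscale <- function(image, method = c("unweighted_mean", "luma_bt601")) {
  method <- match.arg(method)
  image <- validate_raster(image)
  if (is.matrix(image)) {
    gray <- image
  } else {
    r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
    gray <- switch(method,
      unweighted_mean = round_half_up((as.double(r) + g + b) / 3),
      luma_bt601 = round_half_up(0.299 * as.double(r) + 0.587 * g + 0.114 * b)
    )
    gray <- pmin(pmax(gray, 0), 255)
    dim(gray) <- dim(image)[1:2]
    storage.mode(gray) <- "integer"
  }
  attr(gray, "grayscale_method") <- method
  gray
}

#' Rasterize a polygon ROI to a pixel mask
#'
#' Decides, for every pixel of a `width x height` image, whether its center
#' `(col + 0.5, row + 0.5)` (0-based indices, origin top-left, continuous
#' pixel coordinates) lies inside the polygon under the even-odd fill rule.
#' Vertices may extend beyond the image; the mask is clipped to the frame.
#' Implemented as a scanline sweep: per pixel row, the crossings of the
#' polygon edges with the horizontal line through the pixel centers are
#' sorted and alternate inter-crossing spans are filled.
#'
#' @param roi A [polygon_roi()].
#' @param width,height Image dimensions in pixels.
#' @return A `pixel_mask`: a logical `height x width` matrix with attribute
#'   `n_inside`.
#' @examples
#' sq <- polygon_roi(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' m <- rasterize_polygon(sq, width = 20, height = 20)
#' attr(m, "n_inside")   # 100 pixel centers fall inside
#' @export
rasterize_polygon <- function(roi, width, height) {
  roi <- as_polygon_roi(roi)
  stopifnot(width >= 1, height >= 1)
  vx <- roi$vertices$x
  vy <- roi$vertices$y
  n <- length(vx)
  jx <- c(vx[n], vx[-n])   # previous vertex (closing edge included)
  jy <- c(vy[n], vy[-n])
  mask <- matrix(FALSE, nrow = height, ncol = width)
  for (row in seq_len(height) - 1L) {
    yc <- row + 0.5
    crossing <- (vy > yc) != (jy > yc)
    if (!any(crossing)) next
    xint <- vx[crossing] +
      (yc - vy[crossing]) * (jx[crossing] - vx[crossing]) /
      (jy[crossing] - vy[crossing])
    xint <- sort(xint)
    for (k in seq(1L, length(xint) - 1L, by = 2L)) {
      # pixel centers cx with xint[k] <= cx < xint[k + 1]
      lo <- max(ceiling(xint[k] - 0.5), 0)
      hi <- min(ceiling(xint[k + 1] - 0.5) - 1, width - 1L)
      if (lo <= hi) mask[row + 1L, (lo:hi) + 1L] <- !mask[row + 1L, (lo:hi) + 1L]
    }
  }
  structure(mask, n_inside = sum(mask), class = c("pixel_mask", "matrix", "array"))
}

#' Gray-level histogram of the pixels under a mask
#'
#' Tallies the 256-bin histogram of the grayscale intensities at the mask's
#' inside pixels; the histogram total equals the mask's pixel count.
#'
#' @param gray A 1-channel integer matrix (see [to_grayscale()]).
#' @param mask A [rasterize_polygon()] mask of the same dimensions.
#' @return A [gray_histogram()].
#' @export
roi_histogram <- function(gray, mask) {
  gray <- validate_raster(gray)
  if (!is.matrix(gray)) {
    abort("`gray` must be a single-channel image; convert with to_grayscale().",
          class = "chromentropy_unsupported_image")
  }
  if (!identical(dim(gray), dim(mask)[1:2])) {
    abort(sprintf("Dimension mismatch: image is %dx%d but mask is %dx%d.",
                  dim(gray)[1], dim(gray)[2], dim(mask)[1], dim(mask)[2]),
          class = "chromentropy_dimension_mismatch")
  }
  inside <- gray[as.logical(mask)]
  if (length(inside) == 0L) {
    abort("Empty ROI: the polygon covers no pixel centers within the image.",
          class = "chromentropy_empty_roi")
  }
  gray_histogram(tabulate(inside + 1L, nbins = N_LEVELS))
}

#' Entropy of one ROI on one image, end to end
#'
#' The full per-ROI computation: grayscale conversion, polygon
#' rasterization, masked 256-bin histogram, normalization, Shannon entropy.
#' Provenance (conversion method, bin count) is recorded on the result so
#' downstream [relative_entropy()] can refuse cross-convention comparisons.
#'
#' @param image An RGB array or grayscale matrix of 0-255 integers, or a
#'   file path accepted by [read_raster()].
#' @param roi A [polygon_roi()] delineating the region.
#' @param method Grayscale conversion, see [to_grayscale()].
#' @param label ROI identifier carried into the result; defaults to the
#'   polygon's name.
#' @return A one-row [entropy_result()] tibble.
#' @examples
#' img <- matrix(128L, 32, 32)                      # constant-gray frame
#' roi <- polygon_roi(c(2, 20, 20, 2), c(2, 2, 20, 20))
#' compute_roi_entropy(img, roi, label = "patch")   # H = 0 bits
#' @export
compute_roi_entropy <- function(image, roi,
                                method = c("unweighted_mean", "luma_bt601"),
                                label = NULL) {
  method <- match.arg(method)
  if (is.character(image) && length(image) == 1L) image <- read_raster(image)
  roi <- as_polygon_roi(roi)
  gray <- to_grayscale(image, method)
  mask <- rasterize_polygon(roi, width = ncol(gray), height = nrow(gray))
  hist <- roi_histogram(gray, mask)
  h <- shannon_entropy(normalize_histogram(hist))
  entropy_result(label %||% roi$name, h_bits = h,
                 roi_pixels = attr(hist, "total_pixels"),
                 grayscale_method = method)
}

#' Lesion-versus-control entropy analysis
#'
#' Runs [compute_roi_entropy()] for every ROI on one photograph and, when a
#' control ROI is named, pairs each remaining (lesion) ROI against it via
#' [relative_entropy()].  This is the complete workflow behind the
#' command-line `delta` subcommand.
#'
#' @param image Image object or file path.
#' @param rois A named list of [polygon_roi()] objects (names become ROI
#'   labels; unnamed entries fall back to the polygon's own name).
#' @param control Label of the control ROI within `rois`, or `NULL` for
#'   absolute entropies only.
#' @inheritParams compute_roi_entropy
#' @return An object of class `ce_analysis`; use [tidy()] for the per-ROI
#'   table (with `delta_h_bits` when a control is present) and [glance()]
#'   for a one-row summary.
#' @export
entropy_analysis <- function(image, rois, control = NULL,
                             method = c("unweighted_mean", "luma_bt601")) {
  method <- match.arg(method)
  if (is.character(image) && length(image) == 1L) image <- read_raster(image)
  if (inherits(rois, "polygon_roi")) rois <- list(rois)
  labels <- names(rois) %||% rep("", length(rois))
  results <- purrr::map2(rois, labels, function(roi, lab) {
    compute_roi_entropy(image, roi, method = method,
                        label = if (nzchar(lab)) lab else NULL)
  })
  results <- dplyr::bind_rows(results)
  if (!is.null(control) && !control %in% results$label) {
    abort(sprintf("Control ROI '%s' is not among the ROI labels.", control),
          class = "chromentropy_invalid_result")
  }
  structure(list(results = results, control = control, method = method),
            class = "ce_analysis")
}

#' @export
print.ce_analysis <- function(x, ...) {
  cat(sprintf("<entropy analysis: %d ROI(s), grayscale = %s%s>\n",
              nrow(x$results), x$method,
              if (is.null(x$control)) "" else paste0(", control = ", x$control)))
  print(tidy(x))
  invisible(x)
}

#' @rdname entropy_analysis
#' @param x A `ce_analysis` object.
#' @param ... Unused.
#' @method tidy ce_analysis
#' @export
tidy.ce_analysis <- function(x, ...) {
  delta_table(x$results, control_label = x$control)
}

#' @rdname entropy_analysis
#' @method glance ce_analysis
#' @export
glance.ce_analysis <- function(x, ...) {
  tibble(
    n_rois = nrow(x$results),
    n_lesions = nrow(x$results) - as.integer(!is.null(x$control)),
    control_label = x$control %||% NA_character_,
    grayscale_method = x$method,
    bins = N_LEVELS
  )
}

#' Export a pixel mask as a black/white PNG
#'
#' Writes the mask with inside pixels at 255 and outside at 0, for visual
#' quality control of the rasterized ROI.
#'
#' @param mask A [rasterize_polygon()] mask.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.double(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
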