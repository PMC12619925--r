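#' Polygonal region of interest
#'
#' An ordered ring of vertices in continuous pixel coordinates (0-based,
#' origin top-left, y downward) delineating a lesion or perilesional-skin
#' region.  The ring is implicitly closed; at least three vertices and a
#' nonzero enclosed area are required.
#'
#' @param x,y Numeric vertex coordinates, in order around the ring.
#' @param name Text label for the ROI.
#' @return An object of class `polygon_roi`: a list with a `vertices` tibble
#'   (`x`, `y`) and `name`.
#' @examples
#' tri <- polygon_roi(c(0, 4, 0), c(0, 0, 4), name = "lesion")
#' tri
#' @export
polygon_roi <- function(x, y, name = "roi") {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      anyNA(x) || anyNA(y)) {
    abort("Vertices must be equal-length numeric `x` and `y` without NAs.",
          class = "chromentropy_invalid_polygon")
  }
  if (length(x) < 3L) {
    abort(sprintf("A polygon needs at least 3 vertices, got %d.", length(x)),
          class = "chromentropy_invalid_polygon")
  }
  if (abs(shoelace_area(x, y)) <= 0) {
    abort("Degenerate polygon: vertices are collinear (zero area).",
          class = "chromentropy_invalid_polygon")
  }
  structure(list(vertices = tibble(x = as.double(x), y = as.double(y)),
                 name = as.character(name)),
            class = "polygon_roi")
}

# Signed area of the closed ring (shoelace formula); sign reflects winding.
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

as_polygon_roi <- function(roi) {
  if (inherits(roi, "polygon_roi")) return(roi)
  abort("Expected a polygon_roi object (see polygon_roi(), read_roi()).",
        class = "chromentropy_invalid_polygon")
}

#' @export
print.polygon_roi <- function(x, ...) {
  cat(sprintf("<polygon_roi '%s': %d vertices, area %.1f px^2>\n",
              x$name, nrow(x$vertices),
              abs(shoelace_area(x$vertices$x, x$vertices$y))))
  invisible(x)
}

#' @method as_tibble polygon_roi
#' @export
as_tibble.polygon_roi <- function(x, ...) x$vertices

#' Read an ImageJ/Fiji .roi file
#'
#' Decodes the binary ROI format written by ImageJ's selection tools.  Only
#' polygon selections (and freehand selections, which carry the same vertex
#' layout) are supported, matching a polygonal-delineation workflow; other
#' ROI types (rectangle, oval, line, point, ...) are recognized and rejected
#' by name.  Vertices are reconstructed as `left + x_offset`,
#' `top + y_offset` from the stored integer offsets, or taken from the
#' stored float coordinates when the file's sub-pixel resolution flag is
#' set.  The ROI name embedded in the file is used when present, otherwise
#' the file name.
#'
#' @param src Path to a `.roi` file, or a raw vector of its bytes.
#' @return A [polygon_roi()].
#' @export
read_imagej_roi <- function(src) {
  if (is.character(src) && length(src) == 1L) {
    if (!file.exists(src)) {
      abort(sprintf("ROI file not found: '%s'.", src),
            class = "chromentropy_io_error")
    }
    bytes <- readBin(src, "raw", n = file.size(src))
    default_name <- tools::file_path_sans_ext(basename(src))
  } else if (is.raw(src)) {
    bytes <- src
    default_name <- "roi"
  } else {
    abort("`src` must be a file path or raw vector.",
          class = "chromentropy_io_error")
  }
  if (length(bytes) < 64L || rawToChar(bytes[1:4]) != "Iout") {
    abort("Not an ImageJ .roi file (missing 'Iout' magic or truncated header).",
          class = "chromentropy_not_roi_file")
  }
  be_short <- function(off, n = 1L) {
    readBin(bytes[(off + 1L):(off + 2L * n)], "integer",
            n = n, size = 2L, signed = TRUE, endian = "big")
  }
  be_int <- function(off, n = 1L) {
    readBin(bytes[(off + 1L):(off + 4L * n)], "integer",
            n = n, size = 4L, endian = "big")
  }
  be_float <- function(off, n = 1L) {
    readBin(bytes[(off + 1L):(off + 4L * n)], "double",
            n = n, size = 4L, endian = "big")
  }
  version <- be_short(4L)
  type <- as.integer(bytes[7L])
  type_names <- c("polygon", "rectangle", "oval", "line", "freeline",
                  "polyline", "no-roi", "freehand", "traced", "angle",
                  "point")
  if (!type %in% c(0L, 7L)) {
    found <- if (type < length(type_names)) type_names[type + 1L]
             else sprintf("unknown (%d)", type)
    abort(sprintf(
      "Unsupported ROI type '%s': only polygon and freehand selections are supported.",
      found), class = "chromentropy_unsupported_roi_type")
  }
  top <- be_short(8L); left <- be_short(10L)
  n_coords <- be_short(16L)
  if (n_coords < 3L) {
    abort(sprintf("ROI has %d vertices; a polygon needs at least 3.", n_coords),
          class = "chromentropy_invalid_polygon")
  }
  options <- be_short(50L)
  sub_pixel <- version >= 222L && bitwAnd(options, 128L) != 0L
  need <- 64L + 4L * n_coords + if (sub_pixel) 8L * n_coords else 0L
  if (length(bytes) < need) {
    abort("Not an ImageJ .roi file (coordinate block truncated).",
          class = "chromentropy_not_roi_file")
  }
  if (sub_pixel) {
    base <- 64L + 4L * n_coords
    x <- be_float(base, n_coords)
    y <- be_float(base + 4L * n_coords, n_coords)
  } else {
    x <- left + be_short(64L, n_coords)
    y <- top + be_short(64L + 2L * n_coords, n_coords)
  }
  name <- roi_embedded_name(bytes, be_int, be_short) %||% default_name
  polygon_roi(x, y, name = name)
}

# The ROI name lives behind the second header; absent or malformed offsets
# simply mean "no name".
roi_embedded_name <- function(bytes, be_int, be_short) {
  if (length(bytes) < 64L) return(NULL)
  h2 <- be_int(60L)
  if (h2 <= 0L || h2 + 24L > length(bytes)) return(NULL)
  name_off <- be_int(h2 + 16L)
  name_len <- be_int(h2 + 20L)
  if (name_off <= 0L || name_len <= 0L ||
      name_off + 2L * name_len > length(bytes)) return(NULL)
  chars <- be_short(name_off, name_len)
  intToUtf8(chars)
}

#' Read and write polygon ROIs as JSON
#'
#' A portable plain-text dialect for users without Fiji: a JSON object
#' `{"name": ..., "vertices": [[x, y], ...]}` with coordinates in the same
#' continuous pixel space as [polygon_roi()].  Writing preserves coordinates
#' at full double precision so a read-back is exact.
#'
#' @param src JSON text, or a path to a `.json` file.
#' @return `read_polygon_json()` returns a [polygon_roi()];
#'   `write_polygon_json()` returns the JSON text (invisibly when `path` is
#'   given).
#' @examples
#' txt <- write_polygon_json(polygon_roi(c(0, 4, 0), c(0, 0, 4), "lesion"))
#' read_polygon_json(txt)
#' @export
read_polygon_json <- function(src) {
  if (length(src) == 1L && !grepl("[{]", src)) {
    if (!file.exists(src)) {
      abort(sprintf("ROI file not found: '%s'.", src),
            class = "chromentropy_io_error")
    }
    src <- paste(readLines(src, warn = FALSE), collapse = "\n")
  }
  obj <- tryCatch(jsonlite::fromJSON(src, simplifyMatrix = TRUE),
                  error = function(e) {
                    abort(paste0("Invalid polygon JSON: ", conditionMessage(e)),
                          class = "chromentropy_parse_error")
                  })
  v <- obj$vertices
  if (is.null(v) || !is.numeric(unlist(v))) {
    abort("Polygon JSON must have a numeric `vertices` field of [x, y] pairs.",
          class = "chromentropy_parse_error")
  }
  if (!is.matrix(v)) v <- matrix(unlist(v), ncol = 2, byrow = TRUE)
  if (ncol(v) != 2L || nrow(v) < 3L) {
    abort(sprintf("Polygon JSON needs at least 3 [x, y] vertex pairs, got %d.",
                  nrow(v)), class = "chromentropy_invalid_polygon")
  }
  polygon_roi(v[, 1], v[, 2], name = obj$name %||% "roi")
}

#' @rdname read_polygon_json
#' @param roi A [polygon_roi()].
#' @param path Optional output path.
#' @export
write_polygon_json <- function(roi, path = NULL) {
  roi <- as_polygon_roi(roi)
  text <- jsonlite::toJSON(
    list(name = jsonlite::unbox(roi$name),
         vertices = unname(as.matrix(roi$vertices))),
    digits = I(17))
  text <- as.character(text)
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Read a polygon ROI from either supported file format
#'
#' Dispatches on the file extension: `.roi` to [read_imagej_roi()],
#' `.json` to [read_polygon_json()].
#'
#' @param path ROI file path.
#' @return A [polygon_roi()].
#' @export
read_roi <- function(path) {
  switch(tolower(tools::file_ext(path)),
    roi = read_imagej_roi(path),
    json = read_polygon_json(path),
    abort(sprintf("Unsupported ROI format for '%s' (need .roi or .json).",
                  path), class = "chromentropy_io_error")
  )
}
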