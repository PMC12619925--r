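#' Gray-level histogram of a region of interest
#'
#' Constructs a validated 256-bin gray-level histogram, the raw pixel
#' frequencies from which Shannon entropy is computed.  Bin `i + 1` holds the
#' number of pixels with intensity `i` (levels 0 to 255).
#'
#' @param counts Integer vector of length 256: pixel counts per intensity
#'   level, in level order 0..255.  All counts must be non-negative and at
#'   least one must be positive.
#'
#' @return An object of class `gray_histogram`: the integer count vector with
#'   a `total_pixels` attribute.
#' @examples
#' counts <- integer(256)
#' counts[129] <- 100            # 100 pixels at level 128
#' h <- gray_histogram(counts)
#' sum(h)
#' @seealso [normalize_histogram()], [shannon_entropy()], [roi_histogram()]
#' @export
gray_histogram <- function(counts) {
  if (length(counts) != N_LEVELS) {
    abort(sprintf("`counts` must have exactly %d bins, got %d.",
                  N_LEVELS, length(counts)),
          class = "chromentropy_invalid_histogram")
  }
  if (anyNA(counts) || any(counts < 0)) {
    abort("Histogram counts must be non-negative and non-missing.",
          class = "chromentropy_invalid_histogram")
  }
  if (any(counts != trunc(counts))) {
    abort("Histogram counts must be whole numbers of pixels.",
          class = "chromentropy_invalid_histogram")
  }
  total <- sum(as.double(counts))
  if (total < 1) {
    abort("Empty ROI: histogram has zero total pixels.",
          class = "chromentropy_empty_roi")
  }
  structure(as.integer(counts), total_pixels = total,
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  nz <- sum(x > 0)
  cat(sprintf("<gray_histogram: %s pixels over %d of %d levels>\n",
              format(attr(x, "total_pixels"), big.mark = ","), nz, N_LEVELS))
  invisible(x)
}

#' @method as_tibble gray_histogram
#' @export
as_tibble.gray_histogram <- function(x, ...) {
  tibble(level = 0:(N_LEVELS - 1L), count = as.integer(x))
}

#' Convert pixel counts to normalized probabilities
#'
#' Divides each bin count by the ROI pixel total, yielding the relative
#' probability of each gray-level intensity within the ROI.
#'
#' @param hist A [gray_histogram()], or a bare vector of 256 non-negative
#'   counts which is validated first.
#'
#' @return A numeric vector of 256 probabilities summing to 1.
#' @examples
#' counts <- integer(256)
#' counts[1:3] <- c(1, 1, 2)
#' normalize_histogram(counts)[1:3]   # 0.25 0.25 0.50
#' @export
normalize_histogram <- function(hist) {
  if (!inherits(hist, "gray_histogram")) hist <- gray_histogram(hist)
  as.double(hist) / attr(hist, "total_pixels")
}

#' Shannon entropy of a gray-level probability distribution
#'
#' Computes `H = -sum(p_i * log2(p_i))` over the bins with positive
#' probability, in bits.  Zero-probability bins contribute exactly zero
#' (the standard `0 * log2(0) = 0` convention).  For a 256-level histogram
#' the result lies in `[0, 8]` bits.
#'
#' @param p Numeric vector of bin probabilities.  Must be non-negative and
#'   sum to 1 within an absolute tolerance of `1e-9`; anything further from 1
#'   is rejected as unnormalized rather than silently renormalized.
#'
#' @return Entropy in bits (double, full precision).
#' @examples
#' shannon_entropy(rep(1 / 256, 256))        # 8 bits, maximal heterogeneity
#' shannon_entropy(c(1, rep(0, 255)))        # 0 bits, homogeneous region
#' shannon_entropy(c(0.25, 0.25, 0.5))       # 1.5 bits
#' @export
shannon_entropy <- function(p) {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p)) {
    abort("`p` must be a non-empty numeric vector of probabilities.",
          class = "chromentropy_invalid_probability")
  }
  if (any(p < 0) || any(p > 1)) {
    abort("Probabilities must lie in [0, 1].",
          class = "chromentropy_invalid_probability")
  }
  if (abs(sum(p) - 1) > PROB_TOL) {
    abort(sprintf(
      "Probabilities sum to %.12g, not 1: unnormalized input (did you mean normalize_histogram()?).",
      sum(p)), class = "chromentropy_unnormalized")
  }
  pos <- p[p > 0]
  -sum(pos * log2(pos)) + 0   # + 0 normalizes -0 from the degenerate case
}

#' Maximum attainable entropy for a given number of levels
#'
#' The entropy of the uniform distribution over `n_levels` bins,
#' `log2(n_levels)` bits; the upper bound used for validation and reporting.
#'
#' @param n_levels Positive integer number of intensity levels.
#' @return `log2(n_levels)` in bits.
#' @examples
#' max_entropy(256)  # 8
#' max_entropy(2)    # 1
#' @export
max_entropy <- function(n_levels) {
  if (!is.numeric(n_levels) || length(n_levels) != 1L || is.na(n_levels) ||
      n_levels < 1 || n_levels != trunc(n_levels)) {
    abort("`n_levels` must be a single positive integer.",
          class = "chromentropy_invalid_argument")
  }
  log2(n_levels)
}
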