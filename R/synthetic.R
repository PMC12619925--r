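#' Probability distribution over gray levels
#'
#' Builds a 256-bin probability vector concentrated on the given levels —
#' the form the phantom generators take for their intensity models.  With
#' `weights = NULL` the mass is uniform over `levels`.
#'
#' @param levels Integer intensity levels in 0..255.
#' @param weights Optional positive weights, one per level; normalized to
#'   sum to 1.
#' @return A numeric vector of 256 probabilities.
#' @examples
#' level_distribution(64:79)        # uniform over 16 levels: H = 4 bits
#' level_distribution(200)          # a single level: H = 0
#' @export
level_distribution <- function(levels, weights = NULL) {
  if (anyNA(levels) || any(levels < 0) || any(levels > 255) ||
      any(levels != trunc(levels)) || anyDuplicated(levels)) {
    abort("`levels` must be distinct integers in 0..255.",
          class = "chromentropy_invalid_argument")
  }
  weights <- weights %||% rep(1, length(levels))
  if (length(weights) != length(levels) || any(weights <= 0)) {
    abort("`weights` must be positive, one per level.",
          class = "chromentropy_invalid_argument")
  }
  p <- numeric(N_LEVELS)
  p[levels + 1L] <- weights / sum(weights)
  p
}

check_distribution <- function(p, arg = "dist") {
  if (!is.numeric(p) || length(p) != N_LEVELS || anyNA(p) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-12) {
    abort(sprintf(
      "`%s` must be 256 non-negative probabilities summing to 1 (see level_distribution()).",
      arg), class = "chromentropy_invalid_argument")
  }
  p
}

# All phantom randomness flows through one seeded Mersenne-Twister stream so
# a spec (including its seed) maps to exactly one image on every platform.
PHANTOM_GENERATOR <- "Mersenne-Twister"

with_phantom_seed <- function(seed, code) {
  if (length(seed) != 1L || is.na(seed) || seed != trunc(seed)) {
    abort("`seed` must be a single integer.",
          class = "chromentropy_invalid_argument")
  }
  withr::with_seed(as.integer(seed), code,
                   .rng_kind = PHANTOM_GENERATOR,
                   .rng_sample_kind = "Rejection")
}

sample_levels <- function(n, dist) {
  sample.int(N_LEVELS, n, replace = TRUE, prob = dist) - 1L
}

#' Phantom image with an exactly prescribed histogram
#'
#' Emits an image whose full-frame 256-bin histogram equals `counts`
#' bin-for-bin — not approximately, by construction: the multiset of pixel
#' values is laid out deterministically and then spatially permuted with the
#' seeded generator.  Since entropy depends only on the histogram, the
#' image's full-frame entropy equals `shannon_entropy(counts / sum(counts))`
#' exactly, giving an analytically known ground truth for pipeline tests.
#'
#' @param counts 256 non-negative integers summing to `width * height`.
#' @param width,height Image dimensions in pixels.
#' @param seed Integer seed; the same spec and seed yield an identical
#'   image.
#' @param channels 1 for grayscale; 3 replicates gray into RGB so the
#'   grayscale-conversion path is exercised too.
#' @return An integer matrix (or `h x w x 3` array) of 0-255 intensities.
#' @examples
#' counts <- rep(1L, 256)                    # every level exactly once
#' img <- exact_histogram_phantom(counts, width = 16, height = 16)
#' table(img)                                # 256 levels, once each
#' @export
exact_histogram_phantom <- function(counts, width, height, seed = 1L,
                                    channels = 1L) {
  if (length(counts) != N_LEVELS || anyNA(counts) || any(counts < 0) ||
      any(counts != trunc(counts))) {
    abort("`counts` must be 256 non-negative integers.",
          class = "chromentropy_invalid_argument")
  }
  if (sum(counts) != width * height) {
    abort(sprintf("Counts sum to %d but the frame has %d pixels.",
                  sum(counts), width * height),
          class = "chromentropy_invalid_argument")
  }
  values <- rep.int(0:(N_LEVELS - 1L), counts)
  values <- with_phantom_seed(seed, sample(values))
  img <- matrix(as.integer(values), nrow = height, ncol = width, byrow = TRUE)
  if (channels == 3L) img <- replicate_gray(img)
  img
}

replicate_gray <- function(gray) {
  array(rep(gray, 3L), dim = c(nrow(gray), ncol(gray), 3L))
}

#' Two-region lesion/control phantom
#'
#' Synthesizes the lesion-with-internal-control configuration: pixels inside
#' the lesion polygon are i.i.d. draws from `lesion_dist`, all other pixels
#' from `background_dist`, and a control polygon disjoint from the lesion is
#' placed over pure background.  Pixels are spatially independent — the
#' histogram entropy being measured is blind to spatial arrangement, so
#' i.i.d. sampling suffices to exercise it.  The defaults realize a
#' calibration setting with analytically known entropies: a centred
#' 100 x 100-pixel lesion (10,000 pixels) uniform over 16 gray levels
#' (H = 4 bits) on a constant background (H = 0), so the expected relative
#' entropy is 4 bits up to multinomial sampling error.
#'
#' @param width,height Frame dimensions in pixels.
#' @param lesion_dist,background_dist 256-bin probability vectors (see
#'   [level_distribution()]).
#' @param lesion_polygon Lesion [polygon_roi()], strictly inside the frame
#'   with room left for a disjoint control; `NULL` places the default
#'   centred square.
#' @param seed Integer seed; same spec and seed give a byte-identical image.
#' @param channels 1 or 3, as in [exact_histogram_phantom()].
#' @return A list with `image`, `lesion_roi`, `control_roi`, `seed`, and
#'   `generator` (the RNG algorithm recorded for provenance).
#' @examples
#' ph <- lesion_phantom(seed = 7)
#' tidy(entropy_analysis(ph$image,
#'                       list(lesion = ph$lesion_roi, skin = ph$control_roi),
#'                       control = "skin"))
#' @export
lesion_phantom <- function(width = 256L, height = 256L,
                           lesion_dist = level_distribution(64:79),
                           background_dist = level_distribution(200),
                           lesion_polygon = NULL, seed = 1L, channels = 1L) {
  check_distribution(lesion_dist, "lesion_dist")
  check_distribution(background_dist, "background_dist")
  if (is.null(lesion_polygon)) {
    cx <- floor(width / 2); cy <- floor(height / 2)
    lesion_polygon <- polygon_roi(
      c(cx - 50, cx + 50, cx + 50, cx - 50),
      c(cy - 50, cy - 50, cy + 50, cy + 50), name = "lesion")
  }
  lesion_polygon <- as_polygon_roi(lesion_polygon)
  lesion_mask <- rasterize_polygon(lesion_polygon, width, height)
  n_lesion <- attr(lesion_mask, "n_inside")
  if (n_lesion == 0L) {
    abort("Lesion polygon covers no pixels of the frame.",
          class = "chromentropy_empty_roi")
  }
  control_roi <- place_control_roi(lesion_polygon, width, height)
  img <- with_phantom_seed(seed, {
    bg <- sample_levels(width * height, background_dist)
    m <- matrix(as.integer(bg), nrow = height, ncol = width, byrow = TRUE)
    m[as.logical(lesion_mask)] <- sample_levels(n_lesion, lesion_dist)
    m
  })
  if (channels == 3L) img <- replicate_gray(img)
  list(image = img, lesion_roi = lesion_polygon, control_roi = control_roi,
       seed = as.integer(seed), generator = PHANTOM_GENERATOR)
}

# Places a rectangular control ROI in the widest margin between the lesion's
# bounding box and the frame edge; disjointness from the lesion is then
# guaranteed by construction.
place_control_roi <- function(lesion_polygon, width, height) {
  v <- lesion_polygon$vertices
  margins <- c(left = min(v$x), right = width - max(v$x),
               top = min(v$y), bottom = height - max(v$y))
  side <- names(which.max(margins))
  gap <- 2   # clearance from both the lesion bbox and the frame edge
  if (margins[side] < 2 * gap + 4) {
    abort("Lesion polygon leaves no room in the frame for a disjoint control ROI.",
          class = "chromentropy_no_control_room")
  }
  box <- switch(side,
    left   = c(gap, gap, min(v$x) - gap, height - gap),
    right  = c(max(v$x) + gap, gap, width - gap, height - gap),
    top    = c(gap, gap, width - gap, min(v$y) - gap),
    bottom = c(gap, max(v$y) + gap, width - gap, height - gap))
  polygon_roi(c(box[1], box[3], box[3], box[1]),
              c(box[2], box[2], box[4], box[4]), name = "control")
}

#' Plug-in entropy of seeded draws versus the analytic value
#'
#' Draws `n_pixels` i.i.d. gray levels from `dist`, computes the entropy of
#' the empirical histogram (the plug-in estimator), and reports it next to
#' the analytic entropy of `dist`.  The plug-in estimator is negatively
#' biased at finite n and converges to the analytic value as `n_pixels`
#' grows; this function quantifies that error for the validation suite.
#'
#' @param dist A 256-bin probability vector.
#' @param n_pixels Number of draws (at least 1).
#' @param seed Integer seed.
#' @return A one-row tibble with `h_measured`, `h_analytic`, `abs_error`
#'   (bits) and `n_pixels`.
#' @export
empirical_vs_analytic_entropy <- function(dist, n_pixels, seed = 1L) {
  check_distribution(dist)
  if (length(n_pixels) != 1L || is.na(n_pixels) || n_pixels < 1) {
    abort("`n_pixels` must be a positive integer.",
          class = "chromentropy_invalid_argument")
  }
  draws <- with_phantom_seed(seed, sample_levels(n_pixels, dist))
  h_meas <- shannon_entropy(
    normalize_histogram(tabulate(draws + 1L, nbins = N_LEVELS)))
  h_true <- shannon_entropy(dist)
  tibble(h_measured = h_meas, h_analytic = h_true,
         abs_error = abs(h_meas - h_true), n_pixels = as.double(n_pixels))
}
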