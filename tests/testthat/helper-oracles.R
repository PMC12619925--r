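# Independent oracles the implementation is checked against.  These share no
# code with the package internals: the mask oracle casts a ray per pixel
# center and counts edge crossings (pnpoly), rather than scanline filling;
# the entropy oracle tallies pixel values directly with table().

# Even-odd point-in-polygon by ray casting at every pixel center.
oracle_mask <- function(roi, width, height) {
  vx <- roi$vertices$x
  vy <- roi$vertices$y
  n <- length(vx)
  centers <- expand.grid(col = seq_len(width) - 1L, row = seq_len(height) - 1L)
  px <- centers$col + 0.5
  py <- centers$row + 0.5
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- vx[i] + (py[crosses] - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      hit <- which(crosses)[px[crosses] < xint]
      inside[hit] <- !inside[hit]
    }
    j <- i
  }
  matrix(inside, nrow = height, ncol = width, byrow = TRUE)
}

# Entropy straight from a vector of pixel values: empirical frequency of
# every distinct value, -sum(f * log2(f)).
oracle_entropy_pixels <- function(values) {
  f <- as.vector(table(values)) / length(values)
  -sum(f * log2(f))
}

# Histogram straight from pixel values.
oracle_histogram <- function(values) {
  counts <- integer(256)
  for (v in values) counts[v + 1L] <- counts[v + 1L] + 1L
  counts
}

# Random simple-ish polygon (possibly self-intersecting; even-odd handles
# that) with vertices allowed slightly outside the frame.
random_polygon <- function(width, height, n_max = 10L) {
  repeat {
    n <- sample(3:n_max, 1L)
    x <- stats::runif(n, -2, width + 2)
    y <- stats::runif(n, -2, height + 2)
    ok <- tryCatch({polygon_roi(x, y); TRUE}, error = function(e) FALSE)
    if (ok) return(polygon_roi(x, y))
  }
}

random_image <- function(width, height) {
  matrix(sample(0:255, width * height, replace = TRUE),
         nrow = height, ncol = width)
}
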