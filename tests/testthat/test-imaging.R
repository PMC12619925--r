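rgb_pixel <- function(r, g, b) {
  img <- array(0L, c(1, 1, 3))
  img[1, 1, ] <- c(r, g, b)
  img
}

test_that("grayscale conversion matches hand arithmetic for both methods", {
  expect_identical(to_grayscale(rgb_pixel(255, 255, 255))[1, 1], 255L)
  expect_identical(to_grayscale(rgb_pixel(255, 255, 255), "luma_bt601")[1, 1], 255L)
  # round(70 / 3) = 23, half away from zero
  expect_identical(to_grayscale(rgb_pixel(10, 20, 40))[1, 1], 23L)
  # round(29.9 + 117.4 + 5.7) = 153
  expect_identical(to_grayscale(rgb_pixel(100, 200, 50), "luma_bt601")[1, 1], 153L)
  # round(1.0) stays 1 under both channel orders
  expect_identical(to_grayscale(rgb_pixel(1, 2, 0))[1, 1], 1L)
  expect_identical(to_grayscale(rgb_pixel(120, 120, 125), "luma_bt601")[1, 1], 121L)  # 120.57
})

test_that("grayscale on a 1-channel image is the identity", {
  gray <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  out <- to_grayscale(gray, "luma_bt601")
  expect_equal(unclass(out), gray, ignore_attr = TRUE)
})

test_that("unsupported channel counts and bit depths are rejected", {
  bad <- array(0L, c(2, 2, 5))
  expect_error(to_grayscale(bad), class = "chromentropy_unsupported_image")
  expect_error(to_grayscale(matrix(300L, 2, 2)),
               class = "chromentropy_unsupported_image")
  expect_error(to_grayscale(matrix(0.5, 2, 2)),
               class = "chromentropy_unsupported_image")
})

test_that("rasterization fills pixel centers under the even-odd rule", {
  sq <- polygon_roi(c(0, 10, 10, 0), c(0, 0, 10, 10))
  m <- rasterize_polygon(sq, 20, 20)
  expect_identical(attr(m, "n_inside"), 100L)
  expect_true(all(m[1:10, 1:10]))

  tri <- polygon_roi(c(0, 4, 0), c(0, 0, 4))
  m <- rasterize_polygon(tri, 8, 8)
  expect_identical(attr(m, "n_inside"), 6L)
  expect_identical(unclass(m), oracle_mask(tri, 8, 8), ignore_attr = TRUE)
})

test_that("rasterization agrees with the ray-casting oracle on random polygons", {
  set.seed(2024)
  for (i in 1:60) {
    w <- sample(4:40, 1); h <- sample(4:40, 1)
    roi <- random_polygon(w, h)
    m <- rasterize_polygon(roi, w, h)
    expect_identical(unclass(m), oracle_mask(roi, w, h), ignore_attr = TRUE)
    expect_identical(attr(m, "n_inside"), sum(m))
  }
})

test_that("masks are clipped to the frame and degenerate polygons rejected", {
  big <- polygon_roi(c(-5, 50, 50, -5), c(-5, -5, 50, 50))
  m <- rasterize_polygon(big, 10, 10)
  expect_identical(attr(m, "n_inside"), 100L)
  expect_error(polygon_roi(c(0, 1, 2), c(0, 1, 2)),
               class = "chromentropy_invalid_polygon")
  expect_error(polygon_roi(c(0, 1), c(0, 1)),
               class = "chromentropy_invalid_polygon")
})

test_that("convex mask pixel count is within a perimeter of the analytic area", {
  set.seed(5)
  for (i in 1:20) {
    w0 <- runif(1, 3, 30); h0 <- runif(1, 3, 30)
    x0 <- runif(1, 0, 10); y0 <- runif(1, 0, 10)
    rect <- polygon_roi(c(x0, x0 + w0, x0 + w0, x0),
                        c(y0, y0, y0 + h0, y0 + h0))
    m <- rasterize_polygon(rect, 45, 45)
    area <- w0 * h0
    perim <- 2 * (w0 + h0)
    expect_lte(abs(attr(m, "n_inside") - area), perim)
  }
})

test_that("roi_histogram tallies exactly the pixels under the mask", {
  img <- matrix(128L, 20, 20)
  m <- rasterize_polygon(polygon_roi(c(0, 10, 10, 0), c(0, 0, 10, 10)), 20, 20)
  h <- roi_histogram(img, m)
  expect_identical(as.integer(h)[129], 100L)
  expect_identical(sum(h), 100L)

  # full-frame mask totals width x height
  full <- rasterize_polygon(polygon_roi(c(0, 20, 20, 0), c(0, 0, 20, 20)), 20, 20)
  img2 <- random_image(20, 20)
  expect_identical(attr(roi_histogram(img2, full), "total_pixels"), 400)

  # against a per-pixel tally on a random mask
  set.seed(77)
  img3 <- random_image(16, 16)
  repeat {
    m3 <- rasterize_polygon(random_polygon(16, 16), 16, 16)
    if (attr(m3, "n_inside") > 0L) break
  }
  expect_identical(as.integer(roi_histogram(img3, m3)),
                   oracle_histogram(img3[as.logical(m3)]))
})

test_that("empty masks and dimension mismatches are errors", {
  img <- matrix(0L, 10, 10)
  outside <- polygon_roi(c(50, 60, 60, 50), c(50, 50, 60, 60))
  m <- rasterize_polygon(outside, 10, 10)
  expect_error(roi_histogram(img, m), class = "chromentropy_empty_roi")
  m2 <- rasterize_polygon(polygon_roi(c(0, 5, 5, 0), c(0, 0, 5, 5)), 12, 12)
  expect_error(roi_histogram(img, m2),
               class = "chromentropy_dimension_mismatch")
})

test_that("histogram and entropy are invariant under integer translation", {
  set.seed(9)
  patch <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  img <- matrix(0L, 40, 40)
  roi0 <- polygon_roi(c(2, 12, 12, 2), c(2, 2, 12, 12))
  img[3:12, 3:12] <- patch
  h0 <- roi_histogram(img, rasterize_polygon(roi0, 40, 40))
  for (i in 1:5) {
    dx <- sample(0:25, 1); dy <- sample(0:25, 1)
    img_t <- matrix(0L, 40, 40)
    img_t[3:12 + dy, 3:12 + dx] <- patch
    roi_t <- polygon_roi(roi0$vertices$x + dx, roi0$vertices$y + dy)
    h_t <- roi_histogram(img_t, rasterize_polygon(roi_t, 40, 40))
    expect_identical(as.integer(h_t), as.integer(h0))
  }
})

test_that("compute_roi_entropy composes the full per-ROI pipeline", {
  sq <- polygon_roi(c(2, 18, 18, 2), c(2, 2, 18, 18), name = "patch")
  # constant image: perfectly homogeneous, H = 0
  r0 <- compute_roi_entropy(matrix(57L, 24, 24), sq)
  expect_identical(r0$h_bits, 0)
  expect_identical(r0$label, "patch")
  expect_identical(r0$roi_pixels, 256)
  expect_identical(r0$grayscale_method, "unweighted_mean")

  # two equally frequent levels: exactly 1 bit
  img <- matrix(10L, 24, 24)
  img[, seq(2, 24, by = 2)] <- 200L
  r1 <- compute_roi_entropy(img, sq)
  expect_identical(r1$h_bits, 1)

  # exact-histogram phantom: measured H equals the spec's analytic entropy
  counts <- integer(256); counts[c(3, 60, 200) + 1L] <- c(100L, 200L, 100L)
  ph <- exact_histogram_phantom(counts, 20, 20, seed = 3)
  full <- polygon_roi(c(0, 20, 20, 0), c(0, 0, 20, 20))
  r2 <- compute_roi_entropy(ph, full, label = "frame")
  expect_identical(r2$h_bits, shannon_entropy(counts / sum(counts)))
})

test_that("entropy_analysis pairs lesions against the control and tidies", {
  ph <- lesion_phantom(seed = 12)
  fit <- entropy_analysis(ph$image,
                          list(lesion = ph$lesion_roi, skin = ph$control_roi),
                          control = "skin")
  tab <- tidy(fit)
  expect_identical(nrow(tab), 2L)
  expect_true(is.na(tab$delta_h_bits[tab$label == "skin"]))
  expect_identical(tab$delta_h_bits[tab$label == "lesion"],
                   tab$h_bits[1] - tab$h_bits[2])
  g <- glance(fit)
  expect_identical(g$n_lesions, 1L)
  expect_identical(g$control_label, "skin")
  expect_error(entropy_analysis(ph$image, list(a = ph$lesion_roi),
                                control = "missing"),
               class = "chromentropy_invalid_result")
})

test_that("image files round-trip through read_raster", {
  dir <- withr::local_tempdir()
  img <- random_image(12, 9)
  png::writePNG(img / 255, file.path(dir, "g.png"))
  expect_identical(read_raster(file.path(dir, "g.png")), img)
  rgb <- array(sample(0:255, 12 * 9 * 3, replace = TRUE) / 255, c(9, 12, 3))
  tiff::writeTIFF(rgb, file.path(dir, "c.tif"), bits.per.sample = 8L)
  expect_identical(read_raster(file.path(dir, "c.tif")),
                   array(as.integer(round(rgb * 255)), c(9, 12, 3)))
  # alpha is stripped
  rgba <- array(runif(4 * 4 * 4), c(4, 4, 4))
  rgba[] <- round(rgba * 255) / 255
  png::writePNG(rgba, file.path(dir, "a.png"))
  expect_identical(dim(read_raster(file.path(dir, "a.png"))), c(4L, 4L, 3L))
  # 16-bit input is rejected rather than rescaled
  tiff::writeTIFF(matrix(1234 / 65535, 4, 4), file.path(dir, "deep.tif"),
                  bits.per.sample = 16L)
  expect_error(read_raster(file.path(dir, "deep.tif")),
               class = "chromentropy_unsupported_image")
  expect_error(read_raster(file.path(dir, "absent.png")),
               class = "chromentropy_io_error")
})
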