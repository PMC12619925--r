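#' Plot a gray-level histogram
#'
#' Column chart of pixel counts over the 256 intensity levels — the visual
#' companion to the entropy number: flat, wide histograms are
#' high-entropy (variegated), narrow spikes are low-entropy (homogeneous).
#'
#' @param object A [gray_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_raster labs
#'   scale_fill_manual coord_equal theme_minimal
#' @method autoplot gray_histogram
#' @export
autoplot.gray_histogram <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$level, y = .data$count)) +
    geom_col(width = 1) +
    labs(x = "gray level", y = "pixel count",
         subtitle = sprintf("H = %.2f bits",
                            shannon_entropy(normalize_histogram(object)))) +
    theme_minimal()
}

#' Plot per-ROI entropies of an analysis
#'
#' Bar chart of absolute entropy per ROI, with the internal-control ROI
#' (when one is set) distinguished by fill.
#'
#' @param object A [entropy_analysis()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ce_analysis
#' @export
autoplot.ce_analysis <- function(object, ...) {
  tab <- tidy(object)
  tab$role <- ifelse(!is.null(object$control) & tab$label == (object$control %||% ""),
                     "control", "lesion")
  ggplot(tab, aes(x = .data$label, y = .data$h_bits, fill = .data$role)) +
    geom_col() +
    scale_fill_manual(values = c(lesion = "grey25", control = "steelblue")) +
    labs(x = NULL, y = "Shannon entropy H (bits)") +
    theme_minimal()
}

#' Plot a rasterized ROI mask
#'
#' Raster view of a [rasterize_polygon()] mask for visual QC of the
#' discretized polygon (y axis drawn downward to match image coordinates).
#'
#' @param object A `pixel_mask`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pixel_mask
#' @export
autoplot.pixel_mask <- function(object, ...) {
  df <- tibble(
    col = rep(seq_len(ncol(object)) - 1L, each = nrow(object)),
    row = rep(seq_len(nrow(object)) - 1L, times = ncol(object)),
    inside = as.logical(object)
  )
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$inside)) +
    geom_raster() +
    scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white")) +
    coord_equal() +
    labs(x = "x (px)", y = "y (px, downward)") +
    theme_minimal()
}
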