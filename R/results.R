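#' Per-ROI entropy result record
#'
#' Packages one ROI's identity, pixel count and absolute entropy into a
#' one-row tibble, together with the processing provenance (grayscale
#' conversion method and bin count) that determines whether two results are
#' comparable.  This is the record [relative_entropy()] consumes and
#' [write_results()] serializes.
#'
#' @param label Free-text ROI identifier (e.g. `"lesion"`,
#'   `"perilesional skin"`).
#' @param h_bits Absolute Shannon entropy of the ROI histogram, in bits.
#' @param roi_pixels Positive integer count of pixels inside the ROI.
#' @param grayscale_method Grayscale conversion recorded in provenance:
#'   `"unweighted_mean"`, `"luma_bt601"`, or `NA` when unknown (e.g. when
#'   transcribing published values).
#' @param bins Number of histogram bins; fixed at 256 in this version.
#'
#' @return A one-row tibble of class `ce_entropy` with columns `label`,
#'   `roi_pixels`, `h_bits`, `grayscale_method`, `bins`.
#' @examples
#' entropy_result("melanoma", h_bits = 6.94, roi_pixels = 303369)
#' @export
entropy_result <- function(label, h_bits, roi_pixels,
                           grayscale_method = NA_character_,
                           bins = N_LEVELS) {
  stopifnot(length(label) == 1L, length(h_bits) == 1L,
            length(roi_pixels) == 1L)
  if (is.na(h_bits) || h_bits < 0 || h_bits > log2(bins) + 1e-9) {
    abort(sprintf("`h_bits` must lie in [0, %g] for %d bins.",
                  log2(bins), bins),
          class = "chromentropy_invalid_result")
  }
  if (is.na(roi_pixels) || roi_pixels < 1 || roi_pixels != trunc(roi_pixels)) {
    abort("`roi_pixels` must be a positive integer.",
          class = "chromentropy_invalid_result")
  }
  out <- tibble(
    label = as.character(label),
    roi_pixels = as.double(roi_pixels),
    h_bits = as.double(h_bits),
    grayscale_method = as.character(grayscale_method),
    bins = as.integer(bins)
  )
  class(out) <- c("ce_entropy", class(out))
  out
}

#' Relative entropy of a lesion against its internal control
#'
#' Computes the relative entropy `delta H = H_lesion - H_control` in bits:
#' the lesion's absolute entropy minus that of same-patient perilesional
#' skin.  The internal control corrects for baseline skin heterogeneity
#' (age, phototype, photodamage), so the difference is only meaningful when
#' both entropies were computed under the same processing convention; a
#' mismatch in recorded grayscale method or bin count is an error, not a
#' warning.  An `NA` method (unknown provenance, e.g. transcribed published
#' values) is compatible with anything.
#'
#' @param lesion,control One-row [entropy_result()] tibbles.
#'
#' @return A one-row tibble of class `ce_delta` with columns `lesion_label`,
#'   `control_label`, `delta_h_bits`.  `delta_h_bits` may be negative (a
#'   lesion more homogeneous than the surrounding skin).
#' @examples
#' les <- entropy_result("melanoma", 6.94, 303369)
#' ctl <- entropy_result("perilesional skin", 5.75, 261564)
#' relative_entropy(les, ctl)$delta_h_bits   # +1.19
#' @export
relative_entropy <- function(lesion, control) {
  for (r in list(lesion, control)) {
    if (!inherits(r, "ce_entropy") || nrow(r) != 1L) {
      abort("`lesion` and `control` must be one-row entropy_result() tibbles.",
            class = "chromentropy_invalid_result")
    }
  }
  m_l <- lesion$grayscale_method
  m_c <- control$grayscale_method
  if (!is.na(m_l) && !is.na(m_c) && !identical(m_l, m_c)) {
    abort(sprintf(
      "Provenance mismatch: lesion computed with '%s' but control with '%s'; delta H is only meaningful within one grayscale convention.",
      m_l, m_c), class = "chromentropy_provenance_mismatch")
  }
  if (!identical(lesion$bins, control$bins)) {
    abort("Provenance mismatch: lesion and control use different bin counts.",
          class = "chromentropy_provenance_mismatch")
  }
  out <- tibble(
    lesion_label = lesion$label,
    control_label = control$label,
    delta_h_bits = lesion$h_bits - control$h_bits
  )
  class(out) <- c("ce_delta", class(out))
  out
}

#' Assemble a lesion/control results table
#'
#' Binds per-ROI entropy results into one table and fills in the relative
#' entropy column: lesion rows carry `delta_h_bits` against the named
#' control, the control row is left `NA` (rendered as an empty cell in CSV).
#'
#' @param results A tibble of stacked [entropy_result()] rows (e.g. from
#'   `dplyr::bind_rows()`), one per ROI.
#' @param control_label Label of the row to use as the internal control, or
#'   `NULL` for a plain absolute-entropy table with no delta column.
#'
#' @return A tibble with columns `label`, `roi_pixels`, `h_bits`,
#'   `grayscale_method`, `bins` and (when a control is named)
#'   `delta_h_bits`.
#' @examples
#' tab <- dplyr::bind_rows(
#'   entropy_result("nevus", 6.67, 72393),
#'   entropy_result("perilesional skin", 4.39, 70137)
#' )
#' delta_table(tab, control_label = "perilesional skin")
#' @export
delta_table <- function(results, control_label = NULL) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    abort("`results` must be a non-empty table of entropy results.",
          class = "chromentropy_invalid_result")
  }
  results <- as_tibble(results)
  if (is.null(control_label)) return(results)
  idx <- which(results$label == control_label)
  if (length(idx) != 1L) {
    abort(sprintf("Control label '%s' must match exactly one row (matched %d).",
                  control_label, length(idx)),
          class = "chromentropy_invalid_result")
  }
  ctl <- results[idx, ]
  class(ctl) <- c("ce_entropy", class(tibble()))
  delta <- purrr::map_dbl(seq_len(nrow(results)), function(i) {
    if (i == idx) return(NA_real_)
    row <- results[i, ]
    class(row) <- c("ce_entropy", class(tibble()))
    relative_entropy(row, ctl)$delta_h_bits
  })
  dplyr::mutate(results, delta_h_bits = delta)
}

#' Serialize entropy results to CSV or JSON
#'
#' Writes a results table in one of two formats.  CSV mirrors the
#' conventional report layout — one ROI per row, columns
#' `label, roi_pixels, h_bits[, delta_h_bits]` — with entropies rounded to
#' two decimals for display and the delta cell empty on control rows.  JSON
#' carries every field at full double precision plus the processing
#' provenance, so round-trips are bit-exact.  The decimal separator is
#' always `"."` and the delimiter `","`, with no locale variation.
#'
#' @param records A non-empty results tibble from [entropy_result()] /
#'   [delta_table()].
#' @param format `"csv"` or `"json"`.
#' @param path Optional file path; when given, the text is also written
#'   there.
#'
#' @return The serialized text, invisibly when `path` is given.
#' @export
write_results <- function(records, format = c("csv", "json"), path = NULL) {
  format <- match.arg(format)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    abort("`records` must be a non-empty results table.",
          class = "chromentropy_invalid_result")
  }
  records <- as_tibble(records)
  if (format == "csv") {
    cols <- intersect(c("label", "roi_pixels", "h_bits", "delta_h_bits"),
                      names(records))
    disp <- records[cols]
    for (col in intersect(c("h_bits", "delta_h_bits"), cols)) {
      disp[[col]] <- ifelse(is.na(disp[[col]]), "",
                            sprintf("%.2f", disp[[col]]))
    }
    if ("roi_pixels" %in% cols) {
      disp$roi_pixels <- sprintf("%d", as.integer(disp$roi_pixels))
    }
    text <- readr::format_csv(disp, na = "")
  } else {
    text <- jsonlite::toJSON(records, dataframe = "rows", digits = I(17),
                             na = "null", pretty = TRUE)
    text <- paste0(as.character(text), "\n")
  }
  if (!is.null(path)) {
    writeLines(sub("\n$", "", text), path, sep = "\n")
    return(invisible(text))
  }
  text
}
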