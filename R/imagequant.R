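# ROI intensity and coflow-interface quantification.
#
# Coordinates: 0-based, row-major, origin top-left; ROIs are half-open
# rectangles c(row0, row1, col0, col1). The "vertical direction" in which
# the interface is identified maps to image rows (across the channel).

# ROI rectangle -> R index lists
roi_index <- function(frame, roi) {
  stopifnot(length(roi) == 4)
  if (roi[1] < 0 || roi[3] < 0 || roi[2] > nrow(frame) || roi[4] > ncol(frame))
    stop("ROI exceeds the frame bounds")
  if (roi[1] >= roi[2] || roi[3] >= roi[4]) stop("empty ROI")
  list(rows = (roi[1] + 1):roi[2], cols = (roi[3] + 1):roi[4])
}

#' Subtract a background frame
#'
#' Signed difference `frame - background`; negative values are retained
#' (the result lives in a widened intensity range, not 8-bit).
#'
#' @param frame,background Numeric matrices of identical dimension.
#' @return Matrix of signed intensity differences.
#' @export
subtract_background <- function(frame, background) {
  if (!all(dim(frame) == dim(background)))
    stop("subtract_background: frame and background dimensions differ")
  frame - background
}

#' Mean intensity over an ROI
#'
#' @param frame Numeric matrix.
#' @param roi ROI rectangle `c(row0, row1, col0, col1)`, 0-based half-open.
#' @return Arithmetic mean of the ROI pixels.
#' @export
roi_mean_intensity <- function(frame, roi) {
  ix <- roi_index(frame, roi)
  mean(frame[ix$rows, ix$cols])
}

#' Otsu threshold of an 8-bit image
#'
#' The threshold T in 0..254 maximizing the between-class variance of the
#' 256-bin intensity histogram, with pixels `<= T` in the lower class.
#' Ties are broken toward the lower threshold.
#'
#' @param pixels Numeric vector or matrix of intensities in \[0, 255\]
#'   (rounded to integers internally).
#' @return The threshold, an integer in 0..254.
#' @export
otsu_threshold <- function(pixels) {
  px <- round(as.numeric(pixels))
  px <- pmax(pmin(px, 255), 0)
  if (length(unique(px)) < 2)
    stop("otsu_threshold: degenerate histogram, need at least 2 distinct values")
  counts <- tabulate(px + 1L, nbins = 256L)
  n <- length(px)
  levels <- 0:255
  w0 <- cumsum(counts) / n              # P(class0) for T = 0..255
  s0 <- cumsum(counts * levels)
  total <- s0[256]
  mu0 <- ifelse(w0 > 0, s0 / (w0 * n), 0)
  w1 <- 1 - w0
  mu1 <- ifelse(w1 > 0, (total - s0) / (w1 * n), 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2        # between-class variance at T = level
  bcv <- bcv[1:255]                     # T = 255 leaves class1 empty
  as.integer(which.max(bcv) - 1L)       # which.max takes the first (lowest) tie
}

#' Blood-filled width and normalized interface position
#'
#' Counts blood-class pixels per column along the vertical (cross-channel)
#' axis of a binarized viscosity-channel ROI, converts to mm, and averages
#' over columns.
#'
#' @param binary_roi Logical matrix, `TRUE` = blood class.
#' @param pixel_scale Image scale (um/px).
#' @param channel_width Physical channel width w (mm).
#' @return List with `wb` (mm), `alpha_b = wb / channel_width`,
#'   `col_sd` (per-column width dispersion, mm), and `empty` (TRUE, with a
#'   warning, when no blood pixels are present).
#' @export
blood_filled_width <- function(binary_roi, pixel_scale, channel_width = 1) {
  stopifnot(is.logical(binary_roi), is.matrix(binary_roi),
            pixel_scale > 0, channel_width > 0)
  widths_px <- colSums(binary_roi)
  empty <- !any(binary_roi)
  if (empty) warning("blood_filled_width: no blood-class pixels in ROI")
  widths_mm <- widths_px * pixel_scale / 1000
  list(wb = mean(widths_mm),
       alpha_b = mean(widths_mm) / channel_width,
       col_sd = stats::sd(widths_mm),
       empty = empty)
}

#' Interface position from a raw frame
#'
#' Full interface pipeline for one frame: Otsu-binarize the
#' viscosity-channel ROI (threshold computed on that ROI only, so chamber
#' content cannot shift it), assign the blood class to the lower-intensity
#' side, and measure the blood-filled width. Degenerate ROIs (all one
#' intensity: channel entirely blood or entirely reference fluid at the
#' rendered contrast) return `alpha_b` 0 or 1 by mean intensity against
#' `background_hint`.
#'
#' @param frame Numeric matrix, 8-bit scale.
#' @param roi The viscosity-channel ROI rectangle.
#' @param pixel_scale Image scale (um/px).
#' @param channel_width Channel width (mm).
#' @param background_hint Reference-fluid intensity used only to classify a
#'   degenerate single-intensity ROI.
#' @return As [blood_filled_width()], plus `threshold`.
#' @export
interface_alpha <- function(frame, roi, pixel_scale, channel_width = 1,
                            background_hint = NULL) {
  ix <- roi_index(frame, roi)
  sub <- frame[ix$rows, ix$cols]
  if (length(unique(round(as.numeric(sub)))) < 2) {
    hint <- if (is.null(background_hint)) mean(sub) + 1 else background_hint
    all_blood <- mean(sub) < hint - 0.5
    res <- blood_filled_width(matrix(all_blood, nrow(sub), ncol(sub)),
                              pixel_scale, channel_width)
    res$threshold <- NA_integer_
    return(res)
  }
  thr <- otsu_threshold(sub)
  lower <- sub <= thr
  # blood is the darker class
  blood <- if (mean(sub[lower]) <= mean(sub[!lower])) lower else !lower
  res <- blood_filled_width(blood, pixel_scale, channel_width)
  res$threshold <- thr
  res
}
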