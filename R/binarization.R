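# Niblack local thresholding and lumen/stroma partition of the choroid ROI.

#' Niblack threshold parameters
#'
#' Threshold T(x) = m(x) + k * s(x), with m and s the mean and population
#' standard deviation over the square window centred at x. Defaults (31x31
#' window, k = -0.2) follow the common ImageJ Auto Local Threshold settings
#' used for choroidal binarization.
#'
#' @param window_radius_px Half-width of the square window (window side is
#'   `2 * window_radius_px + 1`).
#' @param k Standard-deviation weight; more negative k lowers the threshold
#'   and shrinks the dark (luminal) class.
#' @return An object of class `niblack_params`.
#' @export
niblack_params <- function(window_radius_px = 15L, k = -0.2) {
  window_radius_px <- as.integer(window_radius_px)
  if (window_radius_px < 1L) stop("niblack_params: window_radius_px must be >= 1")
  if (!is.finite(k)) stop("niblack_params: k must be finite")
  structure(list(window_radius_px = window_radius_px, k = k),
            class = "niblack_params")
}

# Windowed box sums by summed-area table; windows are clipped at the image
# border (statistics over in-image pixels only, no padding). For
# integer-valued images every partial sum is an exact integer below 2^53, so
# the result is exact.
box_sums <- function(M, radius) {
  R <- nrow(M); C <- ncol(M)
  acc <- M
  if (R > 1L) for (i in 2:R) acc[i, ] <- acc[i - 1L, ] + acc[i, ]
  if (C > 1L) for (j in 2:C) acc[, j] <- acc[, j - 1L] + acc[, j]
  P <- matrix(0, R + 1L, C + 1L)
  P[-1L, -1L] <- acc
  i <- seq_len(R); j <- seq_len(C)
  top <- pmax(i - radius - 1L, 0L); bot <- pmin(i + radius, R)
  left <- pmax(j - radius - 1L, 0L); right <- pmin(j + radius, C)
  S <- P[bot + 1L, right + 1L, drop = FALSE] - P[top + 1L, right + 1L, drop = FALSE] -
       P[bot + 1L, left + 1L, drop = FALSE] + P[top + 1L, left + 1L, drop = FALSE]
  N <- outer(bot - top, right - left)
  list(S = S, N = N)
}

#' Niblack local threshold map
#'
#' Computes T(x) = m(x) + k * s(x) at every pixel, with windowed statistics
#' from a summed-area table; windows are clipped at image borders and s is
#' the population (divide-by-N) standard deviation.
#'
#' @param image Numeric matrix of intensities.
#' @param params A [niblack_params()].
#' @return Numeric matrix of per-pixel thresholds, same dimensions as
#'   `image`.
#' @examples
#' img <- matrix(0, 3, 3); img[2, 2] <- 9
#' niblack_threshold(img, niblack_params(1, -0.2))[2, 2]  # 1 - 0.2 * sqrt(8)
#' @export
niblack_threshold <- function(image, params = niblack_params()) {
  stopifnot(is.matrix(image), inherits(params, "niblack_params"))
  if (is.integer(image)) storage.mode(image) <- "double"
  bs <- box_sums(image, params$window_radius_px)
  bq <- box_sums(image * image, params$window_radius_px)
  m <- bs$S / bs$N
  m + params$k * sqrt(pmax(bq$S / bs$N - m * m, 0))
}

#' Binarized choroid: lumen / stroma partition of the ROI
#'
#' Applies the Niblack threshold within the choroid ROI (rows between the
#' upper and lower boundary per column): pixels with intensity `<=` threshold
#' are luminal (vessels are hyporeflective; ties go to lumen), the rest
#' stromal. The partition is exact: lumen and stroma are disjoint and their
#' union is the ROI. By default the windowed statistics are restricted to
#' ROI pixels: windows reaching past the choroid's borders would otherwise
#' mix vitreous or sub-scleral background into the local mean and standard
#' deviation and systematically misclassify boundary-adjacent lumen as
#' stroma. `roi_only = FALSE` computes the threshold map over the whole
#' flattened image instead (the convention of whole-image ImageJ workflows).
#'
#' @param image Flattened numeric B-scan matrix.
#' @param seg A `choroid_segmentation` for this image.
#' @param params A [niblack_params()].
#' @param roi_only Compute windowed statistics over ROI pixels only
#'   (default `TRUE`).
#' @param despeckle Apply a 3x3 median filter before thresholding and
#'   classification (default `TRUE`). Speckle is multiplicative and
#'   heavy-tailed; without despeckling the luminal and stromal intensity
#'   distributions overlap and pixelwise classification attenuates extreme
#'   vascularity fractions toward the middle. The median is edge-preserving,
#'   so class identity survives where a mean filter would mix compartments.
#' @return An object of class `binarized_choroid` with logical matrices
#'   `lumen_mask`, `stroma_mask`, `roi_mask`. An empty ROI yields empty
#'   masks, not an error.
#' @export
binarize_choroid <- function(image, seg, params = niblack_params(),
                             roi_only = TRUE, despeckle = TRUE) {
  stopifnot(is.matrix(image), inherits(seg, "choroid_segmentation"))
  if (is.integer(image)) storage.mode(image) <- "double"
  if (length(seg$upper$rows) != ncol(image))
    stop("binarize_choroid: segmentation width does not match image")
  roi <- roi_mask_from_curves(seg$upper$rows, seg$lower$rows, nrow(image))
  if (!any(roi)) {
    empty <- matrix(FALSE, nrow(image), ncol(image))
    return(structure(list(lumen_mask = empty, stroma_mask = empty,
                          roi_mask = empty), class = "binarized_choroid"))
  }
  work <- if (despeckle) median3x3(image) else image
  if (roi_only) {
    r <- params$window_radius_px
    bs <- box_sums(work * roi, r)
    bn <- box_sums(roi + 0, r)
    bq <- box_sums(work * work * roi, r)
    n <- pmax(bn$S, 1)
    m <- bs$S / n
    thr <- m + params$k * sqrt(pmax(bq$S / n - m * m, 0))
  } else {
    thr <- niblack_threshold(work, params)
  }
  lumen <- roi & (work <= thr)
  structure(list(lumen_mask = lumen, stroma_mask = roi & !lumen,
                 roi_mask = roi), class = "binarized_choroid")
}

# 3x3 median filter via a 19-comparison sorting network on the 9 shifted
# copies (replicated borders); vectorized over the whole image.
median3x3 <- function(M) {
  R <- nrow(M); C <- ncol(M)
  ri <- function(d) pmin(pmax(seq_len(R) + d, 1L), R)
  ci <- function(d) pmin(pmax(seq_len(C) + d, 1L), C)
  p <- vector("list", 9L)
  idx <- 1L
  for (dc in -1:1) for (dr in -1:1) {
    p[[idx]] <- M[ri(dr), ci(dc), drop = FALSE]
    idx <- idx + 1L
  }
  op <- function(a, b) {
    lo <- pmin(p[[a]], p[[b]])
    p[[b]] <<- pmax(p[[a]], p[[b]])
    p[[a]] <<- lo
  }
  op(2,3); op(5,6); op(8,9); op(1,2); op(4,5); op(7,8); op(2,3); op(5,6)
  op(8,9); op(1,4); op(6,9); op(5,8); op(4,7); op(2,5); op(3,6); op(5,8)
  op(5,3); op(7,5); op(5,3)
  p[[5]]
}

# ROI between boundary curves: pixel row r belongs to column c's ROI when
# ceiling(upper[c]) <= r < lower[c]; integer curves give rows
# upper .. lower - 1 (thickness = lower - upper pixels).
roi_mask_from_curves <- function(upper, lower, axial_px) {
  C <- length(upper)
  r <- matrix(seq_len(axial_px), axial_px, C)
  up <- matrix(ceiling(upper), axial_px, C, byrow = TRUE)
  lo <- matrix(lower, axial_px, C, byrow = TRUE)
  r >= up & r < lo
}

#' Export lumen / stroma masks as 8-bit PNG
#'
#' Writes `<prefix>_lumen.png` and `<prefix>_stroma.png` with values 0/255.
#'
#' @param bin A `binarized_choroid`.
#' @param prefix File path prefix.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_masks_png <- function(bin, prefix) {
  stopifnot(inherits(bin, "binarized_choroid"))
  paths <- paste0(prefix, c("_lumen.png", "_stroma.png"))
  png::writePNG(bin$lumen_mask + 0, paths[1L])
  png::writePNG(bin$stroma_mask + 0, paths[2L])
  invisible(paths)
}
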