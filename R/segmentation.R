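# RPE detection, B-scan flattening, and choroid boundary delineation by
# dynamic-programming minimum-cost path search.

#' Boundary curve
#'
#' A per-column row index describing a layer boundary across a B-scan.
#' Continuity is bounded: adjacent columns may differ by at most
#' `max_slope_px` rows.
#'
#' @param rows Numeric vector, one row index (1-based) per column.
#' @param kind One of `"rpe"`, `"choroid_upper"`, `"choroid_lower"`.
#' @param axial_px Number of image rows, for range validation.
#' @param max_slope_px Continuity bound in rows per column (default 2).
#' @return An object of class `boundary_curve`.
#' @export
boundary_curve <- function(rows, kind = c("rpe", "choroid_upper", "choroid_lower"),
                           axial_px = NULL, max_slope_px = 2) {
  kind <- match.arg(kind)
  if (!is.numeric(rows) || !length(rows)) stop("boundary_curve: empty rows")
  if (!is.null(axial_px) && (any(rows < 1) || any(rows > axial_px)))
    stop("boundary_curve: rows outside image range 1..", axial_px)
  if (length(rows) > 1L && max(abs(diff(rows))) > max_slope_px + 1e-9)
    stop("boundary_curve: continuity violated (|drow| > ", max_slope_px,
         " between adjacent columns)")
  structure(list(rows = as.numeric(rows), kind = kind,
                 max_slope_px = max_slope_px),
            class = "boundary_curve")
}

# Minimum-cost column-monotone path through a cost image, with per-column
# slope constraint |drow| <= max_slope. Ties resolved toward the smallest
# row (both at the terminal column and in transitions). Infinite cost marks
# forbidden pixels; an all-infinite column means no admissible path.
min_cost_path <- function(cost, max_slope = 2L) {
  R <- nrow(cost); C <- ncol(cost)
  if (!any(is.finite(cost))) stop("min_cost_path: no admissible path")
  offs <- seq.int(-max_slope, max_slope)
  D <- cost[, 1L]
  ptr <- matrix(0L, R, C)
  for (cc in seq_len(C)[-1L]) {
    best <- rep(Inf, R)
    barg <- integer(R)
    for (o in offs) {
      # candidate predecessor row r + o feeding row r; offsets ascend, so
      # strict improvement keeps the smallest predecessor row on ties
      if (o >= 0L) cand <- c(D[seq.int(1L + o, R)], rep(Inf, o))
      else cand <- c(rep(Inf, -o), D[seq_len(R + o)])
      upd <- cand < best
      if (any(upd)) { best[upd] <- cand[upd]; barg[upd] <- o }
    }
    D <- cost[, cc] + best
    ptr[, cc] <- barg
    if (!any(is.finite(D))) stop("min_cost_path: no admissible path")
  }
  path <- integer(C)
  path[C] <- which.min(D)
  for (cc in seq.int(C, 2L)) path[cc - 1L] <- path[cc] + ptr[path[cc], cc]
  path
}

# Median-filter a row profile and clamp successive differences to the slope
# bound, restoring the boundary-curve continuity invariant after per-column
# refinement.
slope_limit <- function(x, max_slope) {
  x <- round(stats::runmed(x, 7L))
  for (cc in seq_along(x)[-1L])
    x[cc] <- min(max(x[cc], x[cc - 1L] - max_slope), x[cc - 1L] + max_slope)
  as.integer(x)
}

# Asymmetric axial edge score: mean intensity over width_above rows above
# each pixel minus mean over width_below rows from the pixel down, windows
# clipped at the frame. Peaks at the first row of a dark region under a
# bright one.
edge_score_axial <- function(img, width_above = 3L, width_below = 9L) {
  R <- nrow(img)
  cs <- rbind(0, apply(img, 2L, cumsum))
  r <- seq_len(R)
  a_lo <- pmax(r - width_above, 1L); a_hi <- pmax(r - 1L, 1L)
  n_a <- pmax(a_hi - a_lo + 1L, 1L)
  above <- (cs[a_hi + 1L, , drop = FALSE] - cs[a_lo, , drop = FALSE]) / n_a
  b_hi <- pmin(r + width_below - 1L, R)
  n_b <- b_hi - r + 1L
  below <- (cs[b_hi + 1L, , drop = FALSE] - cs[r, , drop = FALSE]) / n_b
  out <- above - below
  out[1L, ] <- 0  # no rows above the frame
  out
}

smooth_axial <- function(img, width = 3L) {
  # moving average down each column (along depth), window clipped at edges
  R <- nrow(img)
  cs <- apply(img, 2L, cumsum)
  h <- width %/% 2L
  top <- pmax(seq_len(R) - h - 1L, 0L)
  bot <- pmin(seq_len(R) + h, R)
  n <- bot - top
  up <- rbind(0, cs)
  (up[bot + 1L, , drop = FALSE] - up[top + 1L, , drop = FALSE]) / n
}

#' Detect the retinal pigment epithelium reflection
#'
#' Finds, per column, the row of the brightest axially smoothed band and
#' regularizes it into a continuous curve by a minimum-cost path through the
#' negative smoothed intensity, with slope bound `max_slope_px` rows/column.
#'
#' @param image Numeric B-scan matrix (rows = depth).
#' @param max_slope_px Continuity bound (default 2).
#' @param smooth_px Axial smoothing window (default 3).
#' @return A `boundary_curve` of kind `"rpe"`.
#' @export
detect_rpe <- function(image, max_slope_px = 2L, smooth_px = 3L) {
  stopifnot(is.matrix(image))
  if (max(image) <= 0 || diff(range(image)) == 0)
    stop("detect_rpe: detection failure, image has no bright band")
  sm <- smooth_axial(image, smooth_px)
  path <- min_cost_path(-sm, max_slope_px)
  boundary_curve(path, "rpe", axial_px = nrow(image), max_slope_px = max_slope_px)
}

#' Flatten a B-scan on the RPE reflection
#'
#' Shifts each column vertically by an integer so the detected RPE lies on a
#' single row (the median detected RPE row), removing acquisition tilt.
#' Vacated pixels are zero-filled; shifts are returned so downstream truth
#' bookkeeping can map coordinates. Shift-only: per-column intensities are
#' preserved (up to pixels pushed out of frame).
#'
#' @param image Numeric B-scan matrix.
#' @param rpe A `boundary_curve` of kind `"rpe"` for this image.
#' @return List with `image` (flattened matrix), `shift` (integer per-column
#'   shift applied, positive = moved down), `target_row`.
#' @export
flatten_bscan <- function(image, rpe) {
  stopifnot(is.matrix(image), inherits(rpe, "boundary_curve"))
  if (length(rpe$rows) != ncol(image))
    stop("flatten_bscan: curve length does not match image width")
  R <- nrow(image)
  target <- round(stats::median(rpe$rows))
  shift <- as.integer(target - round(rpe$rows))
  if (any(abs(shift) > R / 2))
    stop("flatten_bscan: flattening error, shift exceeds half the frame")
  out <- matrix(0, R, ncol(image))
  for (cc in seq_len(ncol(image))) {
    s <- shift[cc]
    src <- seq.int(max(1L, 1L - s), min(R, R - s))
    out[src + s, cc] <- image[src, cc]
  }
  list(image = out, shift = shift, target_row = target)
}

apply_column_shift <- function(mat, shift, fill = 0) {
  R <- nrow(mat)
  out <- matrix(fill, R, ncol(mat))
  for (cc in seq_len(ncol(mat))) {
    s <- shift[cc]
    src <- seq.int(max(1L, 1L - s), min(R, R - s))
    if (length(src)) out[src + s, cc] <- mat[src, cc]
  }
  out
}

#' Choroid segmentation result
#'
#' Bundles the RPE, upper and lower choroid boundary curves of one flattened
#' B-scan, plus the flattening shift applied. Invariants:
#' `rpe <= upper <= lower` per column.
#'
#' @param rpe,upper,lower `boundary_curve` objects.
#' @param flatten_shift Integer per-column shift used to flatten the scan.
#' @return An object of class `choroid_segmentation`.
#' @export
choroid_segmentation <- function(rpe, upper, lower, flatten_shift = NULL) {
  stopifnot(inherits(rpe, "boundary_curve"), inherits(upper, "boundary_curve"),
            inherits(lower, "boundary_curve"))
  if (length(upper$rows) != length(lower$rows) ||
      length(rpe$rows) != length(upper$rows))
    stop("choroid_segmentation: curve lengths differ")
  if (any(upper$rows > lower$rows))
    stop("choroid_segmentation: upper boundary below lower boundary")
  if (any(rpe$rows > upper$rows))
    stop("choroid_segmentation: RPE below the upper choroid boundary")
  structure(list(rpe = rpe, upper = upper, lower = lower,
                 flatten_shift = flatten_shift),
            class = "choroid_segmentation")
}

#' Delineate the choroid on a flattened B-scan
#'
#' The upper boundary is the bottom edge of the RPE band: per column, the
#' strongest bright-to-dark axial transition within `search_px` rows below
#' the RPE, regularized by a minimum-cost path. The lower boundary (the
#' choroid-sclera interface) is the minimum-cost left-to-right path through
#' the negative downward intensity gradient (axially smoothed, 3 px),
#' constrained at least `min_thickness_px` below the upper boundary. If no
#' appreciable bright-to-dark transition exists below the upper boundary
#' (an effectively absent choroid band), the boundaries are returned
#' coincident.
#'
#' @param image Flattened numeric B-scan matrix.
#' @param rpe The (post-flattening) RPE `boundary_curve`.
#' @param min_thickness_px Minimum band thickness enforced between upper and
#'   lower (default 5), preventing collapse onto the RPE under noise.
#' @param search_px Search depth below the RPE for the band's bottom edge.
#' @param max_slope_px Continuity bound for both boundaries.
#' @param smooth_lateral_px Lateral smoothing width for the lower-boundary
#'   cost image (default 31); chosen wider than a vessel cross-section so
#'   luminal vessels abutting the choroid-sclera interface do not capture
#'   the path, while the interface edge itself, coherent across columns,
#'   survives the smoothing.
#' @return A `choroid_segmentation` (with `flatten_shift` unset).
#' @export
segment_choroid <- function(image, rpe, min_thickness_px = 5L,
                            search_px = 12L, max_slope_px = 2L,
                            smooth_lateral_px = 31L) {
  stopifnot(is.matrix(image), inherits(rpe, "boundary_curve"))
  R <- nrow(image); C <- ncol(image)
  sm <- smooth_axial(image, 3L)
  # downward gradient: positive where a bright row sits above a dark row
  grad <- rbind(sm[-R, , drop = FALSE] - sm[-1L, , drop = FALSE], 0)
  grad <- smooth_axial(grad, 3L)
  # vessel-suppressed interface score for the lower boundary: on the
  # laterally smoothed image, brightness over a short window above minus
  # brightness over a longer window below. Sustained darkness below
  # distinguishes the sclera from a vessel interior, and the lateral
  # smoothing (wider than a vessel cross-section) suppresses blob edges
  # while the interface, coherent across columns, survives.
  sml <- t(smooth_axial(t(sm), smooth_lateral_px))
  score_l <- edge_score_axial(sml, width_above = 3L, width_below = 9L)

  # upper boundary: bottom edge of the RPE band. The band runs parallel to
  # the detected RPE curve, so its bottom-edge offset is estimated once per
  # image as the offset (within search_px below the RPE) maximizing the
  # column-averaged bright-to-dark transition; this is immune to luminal
  # vessels abutting the band, which would capture a per-column search.
  rpe_r <- pmin(pmax(round(rpe$rows), 1L), R)
  offs <- 0:search_px
  mean_drop <- vapply(offs, function(o) {
    rr <- pmin(rpe_r + o, R - 1L)
    mean(grad[cbind(rr, seq_len(C))])
  }, numeric(1))
  o_star <- offs[which.max(mean_drop)]
  upper <- pmin(rpe_r + o_star + 1L, R)  # first row below the band

  # lower boundary: the interface-score path, at least min_thickness below
  # the upper boundary; the score peaks at the first sub-choroidal row
  cost_l <- -score_l
  admissible_from <- pmin(upper + min_thickness_px, R)
  row_idx <- seq_len(R)
  for (cc in seq_len(C)) cost_l[row_idx < admissible_from[cc], cc] <- Inf
  lower <- min_cost_path(cost_l, max_slope_px)
  # lateral smoothing at a fixed row blurs the undulating boundary and
  # biases the path shallow; re-estimate in a boundary-aligned frame, where
  # columns are shifted onto the first-pass path before smoothing, so the
  # residual to find is small and the blur disappears
  w_off <- 6L
  offs2 <- seq.int(-w_off, w_off)
  aligned <- matrix(0, length(offs2), C)
  for (cc in seq_len(C))
    aligned[, cc] <- sm[pmin(pmax(lower[cc] + offs2, 1L), R), cc]
  al_sm <- t(smooth_axial(t(aligned), smooth_lateral_px))
  cost2 <- -edge_score_axial(al_sm, 3L, 6L)
  for (cc in seq_len(C))
    cost2[lower[cc] + offs2 < admissible_from[cc], cc] <- Inf
  off_path <- min_cost_path(cost2, 1L)
  lower <- lower + offs2[off_path]
  lower <- pmax(pmin(slope_limit(lower, max_slope_px), R), admissible_from)

  # degenerate band: no real transition below the upper edge
  upper_strength <- mean(grad[cbind(pmax(upper - 1L, 1L), seq_len(C))])
  lower_strength <- mean(score_l[cbind(lower, seq_len(C))])
  if (!is.finite(lower_strength) || lower_strength < 0.05 * max(upper_strength, 0)) {
    lower <- upper
  }

  choroid_segmentation(
    rpe = boundary_curve(pmin(rpe_r, upper), "rpe", R, max_slope_px),
    upper = boundary_curve(upper, "choroid_upper", R, max_slope_px),
    lower = boundary_curve(pmax(lower, upper), "choroid_lower", R, max_slope_px)
  )
}

#' Wrap externally supplied choroid boundaries
#'
#' Accepts upper/lower boundary curves produced elsewhere (e.g. by a
#' learning-based segmentation) and validates them against the container
#' invariants; the RPE curve is set to the upper boundary.
#'
#' @param image The B-scan the curves belong to (for range validation).
#' @param upper,lower `boundary_curve` objects or plain numeric row vectors.
#' @return A `choroid_segmentation`.
#' @export
use_external_boundaries <- function(image, upper, lower) {
  stopifnot(is.matrix(image))
  as_curve <- function(x, kind) {
    if (inherits(x, "boundary_curve"))
      boundary_curve(x$rows, kind, axial_px = nrow(image),
                     max_slope_px = x$max_slope_px)
    else boundary_curve(x, kind, axial_px = nrow(image))
  }
  up <- as_curve(upper, "choroid_upper")
  lo <- as_curve(lower, "choroid_lower")
  choroid_segmentation(rpe = as_curve(up$rows, "rpe"), upper = up, lower = lo)
}

#' Export / import segmentation boundaries as CSV
#'
#' One CSV per B-scan with columns `column_index, rpe_row, upper_row,
#' lower_row` (1-based indices).
#'
#' @param seg A `choroid_segmentation`.
#' @param path CSV file path.
#' @return For the writer, `path` invisibly; for the reader, a
#'   `choroid_segmentation`.
#' @export
write_boundaries_csv <- function(seg, path) {
  stopifnot(inherits(seg, "choroid_segmentation"))
  df <- data.frame(column_index = seq_along(seg$upper$rows),
                   rpe_row = seg$rpe$rows, upper_row = seg$upper$rows,
                   lower_row = seg$lower$rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boundaries_csv
#' @export
read_boundaries_csv <- function(path) {
  df <- utils::read.csv(path)
  choroid_segmentation(
    rpe = boundary_curve(df$rpe_row, "rpe"),
    upper = boundary_curve(df$upper_row, "choroid_upper"),
    lower = boundary_curve(df$lower_row, "choroid_lower")
  )
}
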