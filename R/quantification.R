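# Magnification-corrected polar volumetrics: luminal / stromal / total
# choroidal volume and CVI over macular rings, from binarized radial B-scans.

#' Macular ring specification
#'
#' Rings are given as (inner, outer) *diameters* in mm around the fovea,
#' following the ETDRS-grid convention; the defaults are the central 0-3 mm
#' disc, the 3-6 mm annulus, and the whole 0-6 mm disc. A column at radius r
#' belongs to a ring when `inner/2 <= r < outer/2`, so the 0-3 and 3-6 rings
#' partition the 0-6 disc exactly.
#'
#' @param rings List of numeric pairs `c(inner_diameter_mm, outer_diameter_mm)`.
#' @return A data.frame of class `ring_spec` with columns `ring`, `inner_mm`,
#'   `outer_mm`.
#' @export
ring_spec <- function(rings = list(c(0, 3), c(3, 6), c(0, 6))) {
  if (!length(rings)) stop("ring_spec: at least one ring required")
  inner <- vapply(rings, `[`, numeric(1), 1L)
  outer <- vapply(rings, `[`, numeric(1), 2L)
  if (any(inner < 0) || any(outer <= inner))
    stop("ring_spec: each ring needs 0 <= inner < outer")
  structure(data.frame(ring = sprintf("%g-%g", inner, outer),
                       inner_mm = inner, outer_mm = outer,
                       stringsAsFactors = FALSE),
            class = c("ring_spec", "data.frame"))
}

#' Ocular magnification correction (Bennett's formula)
#'
#' Lateral on-image distances scale with the eye's axial length. Bennett's
#' relation q(AL) = 0.01306 (AL - 1.82) mm/deg links fundus distance to image
#' distance; the device-specific constant cancels in the ratio, so the
#' correction applied to the nominal lateral pixel pitch is
#' q(AL) / q(AL_ref), exactly 1 for an eye at the reference axial length.
#' Axial pixel pitch is unaffected.
#'
#' @param axial_length_mm Subject axial length (mm).
#' @param reference_al_mm Reference (emmetropic) axial length the device
#'   calibration assumes; default 24.46 mm.
#' @return Scalar lateral scale factor.
#' @examples
#' bennett_lateral_scale(25.47)  # myopic eye, scale > 1
#' @export
bennett_lateral_scale <- function(axial_length_mm, reference_al_mm = 24.46) {
  if (axial_length_mm <= 1.82 || reference_al_mm <= 1.82)
    stop("bennett_lateral_scale: axial length must exceed 1.82 mm")
  (0.01306 * (axial_length_mm - 1.82)) / (0.01306 * (reference_al_mm - 1.82))
}

#' Radial distance of each A-line from the fovea
#'
#' Radial scans intersect at the fovea; column c of any B-scan sits at fundus
#' radius `|c - fovea_col| * lateral_mm_per_px * scale`, the two sides of the
#' fovea belonging to the B-scan's two opposite semi-meridians.
#'
#' @param geometry A [scan_geometry()].
#' @param fovea_col Fovea-centre column (1-based).
#' @param scale Lateral magnification correction from
#'   [bennett_lateral_scale()].
#' @return Numeric vector of length `n_alines`, radius in mm per column.
#' @export
aline_radii <- function(geometry, fovea_col, scale = 1) {
  stopifnot(inherits(geometry, "scan_geometry"), scale > 0)
  lat <- geometry$scan_width_mm / geometry$n_alines
  abs(seq_len(geometry$n_alines) - fovea_col) * lat * scale
}

#' Ratio of luminal to total choroidal volume
#'
#' @param LV Luminal volume (mm^3).
#' @param TCV Total choroidal volume (mm^3); `TCV = 0` yields `NA` (CVI
#'   undefined, not zero).
#' @return CVI as a fraction in `[0, 1]` (`NA` where undefined).
#' @export
cvi <- function(LV, TCV) {
  if (any(LV < 0 | TCV < 0, na.rm = TRUE) || any(LV > TCV + 1e-12, na.rm = TRUE))
    stop("cvi: need 0 <= LV <= TCV")
  ifelse(TCV > 0, LV / TCV, NA_real_)
}

# Shared polar integration rule. Takes per-scan per-column pixel counts of
# lumen and total (ROI) compartments and integrates
#   V = sum_columns  h(c) * r(c) * dr * dtheta
# over the 2 * n_radials semi-meridians, where h(c) = count * axial_mm_per_px,
# dr = lateral_mm_per_px * scale and dtheta = pi / n_radials. The fovea column
# contributes nothing (r = 0). Used identically by sector_volumes() and by
# the phantom ground-truth oracle.
polar_integrate_counts <- function(lumen_counts, total_counts, geometry,
                                   fovea_col, scale, rings) {
  stopifnot(inherits(rings, "ring_spec"))
  px <- mm_per_px(geometry)
  dr <- px[["lateral"]] * scale
  dtheta <- pi / geometry$n_radials
  r <- aline_radii(geometry, fovea_col, scale)
  w <- r * dr * dtheta * px[["axial"]]  # per-pixel volume weight per column
  lum_col <- colSums(do.call(rbind, lumen_counts))   # summed over scans
  tot_col <- colSums(do.call(rbind, total_counts))
  out <- rings
  out$LV_mm3 <- out$SV_mm3 <- out$TCV_mm3 <- NA_real_
  for (i in seq_len(nrow(rings))) {
    sel <- r >= rings$inner_mm[i] / 2 & r < rings$outer_mm[i] / 2
    lv <- sum(lum_col[sel] * w[sel])
    tcv <- sum(tot_col[sel] * w[sel])
    out$LV_mm3[i] <- lv
    out$TCV_mm3[i] <- tcv
    out$SV_mm3[i] <- tcv - lv
  }
  out$CVI <- cvi(out$LV_mm3, out$TCV_mm3)
  class(out) <- c("regional_volumes", "data.frame")
  attr(out, "scale") <- scale
  out
}

count_mask_columns <- function(mask) .colSums(mask, nrow(mask), ncol(mask))

#' Regional choroidal volumes from binarized radial B-scans
#'
#' Integrates the lumen / stroma / ROI masks of one binarized B-scan per
#' radial angle into luminal (LV), stromal (SV) and total (TCV) choroidal
#' volume and CVI per macular ring. Each semi-meridian represents an angular
#' sector of width pi / n_radials; a column's full thickness is assigned to
#' the ring containing its centre radius.
#'
#' @param binarized List of `n_radials` [binarize_choroid()] results, ordered
#'   by angle.
#' @param geometry A [scan_geometry()].
#' @param fovea_col Fovea-centre column (1-based).
#' @param scale Lateral magnification correction ([bennett_lateral_scale()]).
#' @param rings A [ring_spec()].
#' @return A `regional_volumes` data.frame: one row per ring with columns
#'   `LV_mm3`, `SV_mm3`, `TCV_mm3`, `CVI` (fraction; `NA` where TCV = 0).
#' @export
sector_volumes <- function(binarized, geometry, fovea_col, scale = 1,
                           rings = ring_spec()) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (length(binarized) != geometry$n_radials)
    stop("sector_volumes: expected one binarized B-scan per radial angle (",
         geometry$n_radials, "), got ", length(binarized))
  lum <- lapply(binarized, function(b) count_mask_columns(b$lumen_mask))
  tot <- lapply(binarized, function(b) count_mask_columns(b$roi_mask))
  if (any(vapply(lum, length, 1L) != geometry$n_alines))
    stop("sector_volumes: mask width does not match geometry n_alines")
  polar_integrate_counts(lum, tot, geometry, fovea_col, scale, rings)
}

#' @export
print.regional_volumes <- function(x, ...) {
  cat("Regional choroidal volumes (lateral scale ",
      format(attr(x, "scale") %||% 1, digits = 4), ")\n", sep = "")
  df <- data.frame(ring = x$ring,
                   LV_mm3 = round(x$LV_mm3, 3),
                   SV_mm3 = round(x$SV_mm3, 3),
                   TCV_mm3 = round(x$TCV_mm3, 3),
                   CVI_pct = round(100 * x$CVI, 2))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
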