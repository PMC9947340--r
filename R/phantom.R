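# Synthetic radial SS-OCT phantom: a choroid band with dark luminal blobs in
# brighter stroma under a hyperreflective RPE band, with image tilt and
# multiplicative speckle, plus full ground truth for every pipeline stage.

#' Phantom generation parameters
#'
#' Defaults emulate a macular radial acquisition of a healthy choroid: a
#' ~0.30 mm choroid band with smooth boundary undulation, a luminal (vessel)
#' fraction of 0.59, a 4 px hyperreflective RPE band, per-scan linear tilt up
#' to +/-5 degrees, and multiplicative gamma speckle with 4 looks (the
#' severity expected of a frame-averaged B-scan). Intensity levels are free
#' parameters of the phantom (8-bit defaults: stroma 170, lumen 40, RPE 230,
#' background 12); real acquisitions publish no intensity statistics, so
#' pipeline accuracy should be read as a function of contrast and noise.
#'
#' @param geometry A [scan_geometry()].
#' @param mean_choroid_thickness_mm Mean band thickness (mm).
#' @param thickness_undulation_mm Amplitude of the smooth (band-limited)
#'   boundary undulation (mm).
#' @param target_luminal_fraction Desired lumen / choroid pixel fraction,
#'   in (0, 1); realized fraction is within +/-0.03 of this.
#' @param blob_radius_px_range Min/max semi-axes (px) of the elliptical
#'   luminal blobs; lateral semi-axes are drawn from the full range, axial
#'   semi-axes from the lower half (vessel cross-sections are elongated).
#' @param tilt_deg Per-scan tilt drawn uniformly in `[-tilt_deg, tilt_deg]`.
#' @param speckle_looks Shape parameter of the unit-mean multiplicative
#'   gamma speckle; `Inf` disables noise.
#' @param stroma_level,lumen_level,rpe_level,background_level,retina_level
#'   Mean intensities of the level map (must satisfy
#'   `stroma_level > lumen_level >= background_level`).
#' @param bit_depth Quantization, 8 or 16.
#' @param seed Integer RNG seed; equal seeds give bit-identical phantoms.
#' @param subject,label,fovea_col Session metadata; defaults are an
#'   emmetropic-reference subject, control/baseline, centre column.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(geometry = scan_geometry(),
                           mean_choroid_thickness_mm = 0.30,
                           thickness_undulation_mm = 0.05,
                           target_luminal_fraction = 0.59,
                           blob_radius_px_range = c(2, 7),
                           tilt_deg = 3,
                           speckle_looks = 4,
                           stroma_level = 170, lumen_level = 40,
                           rpe_level = 230, background_level = 12,
                           retina_level = 95,
                           bit_depth = 8L, seed = 1L,
                           subject = subject_meta("phantom", 24.46, 25),
                           label = session_label("control", "baseline"),
                           fovea_col = NULL) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (target_luminal_fraction <= 0 || target_luminal_fraction >= 1)
    stop("phantom_params: target_luminal_fraction must be in (0, 1)")
  if (!(stroma_level > lumen_level && lumen_level >= background_level))
    stop("phantom_params: need stroma_level > lumen_level >= background_level")
  if (speckle_looks < 1) stop("phantom_params: speckle_looks must be >= 1")
  if (length(blob_radius_px_range) != 2L ||
      blob_radius_px_range[1] < 1 || diff(blob_radius_px_range) < 0)
    stop("phantom_params: invalid blob_radius_px_range")
  if (is.null(fovea_col)) fovea_col <- geometry$n_alines %/% 2L + 1L
  structure(list(geometry = geometry,
                 mean_choroid_thickness_mm = mean_choroid_thickness_mm,
                 thickness_undulation_mm = thickness_undulation_mm,
                 target_luminal_fraction = target_luminal_fraction,
                 blob_radius_px_range = blob_radius_px_range,
                 tilt_deg = tilt_deg, speckle_looks = speckle_looks,
                 stroma_level = stroma_level, lumen_level = lumen_level,
                 rpe_level = rpe_level, background_level = background_level,
                 retina_level = retina_level,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed),
                 subject = subject, label = label,
                 fovea_col = as.integer(fovea_col)),
            class = "phantom_params")
}

# Smooth band-limited curve: sum of 3 low-frequency cosines with random
# phases, scaled to the requested amplitude (max |value| = amplitude).
smooth_undulation <- function(C, amplitude_px) {
  if (amplitude_px <= 0) return(numeric(C))
  x <- seq_len(C) / C
  u <- numeric(C)
  for (f in 1:3) u <- u + stats::runif(1, 0.3, 1) * cos(2 * pi * f * x + stats::runif(1, 0, 2 * pi))
  if (max(abs(u)) > 0) u <- u * amplitude_px / max(abs(u))
  u
}

# Place random ellipses in the band until the lumen fraction reaches the
# target; returns the logical lumen mask. Errors if the target is not
# reachable (blob packing infeasible).
place_blobs <- function(R, C, upper, lower, target, rad_range) {
  mask <- matrix(FALSE, R, C)
  band_px <- sum(pmax(lower - upper, 0))
  if (band_px == 0L) return(mask)
  thick <- lower - upper
  max_iter <- 2000L + ceiling(40L * band_px / pi / max(rad_range[1]^2, 1))
  frac <- 0
  it <- 0L
  while (frac < target) {
    it <- it + 1L
    if (it > max_iter)
      stop("generate_phantom: infeasible blob packing for requested luminal fraction")
    cx <- sample.int(C, 1L)
    if (thick[cx] <= 0L) next
    cy <- upper[cx] + stats::runif(1) * thick[cx]
    a <- stats::runif(1, rad_range[1], rad_range[2])                 # lateral
    b <- stats::runif(1, rad_range[1], max(rad_range[1], rad_range[2] / 2))  # axial
    cols <- max(1L, floor(cx - a)):min(C, ceiling(cx + a))
    rows <- max(1L, floor(cy - b)):min(R, ceiling(cy + b))
    dx <- (matrix(cols, length(rows), length(cols), byrow = TRUE) - cx) / a
    dy <- (matrix(rows, length(rows), length(cols)) - cy) / b
    inside <- dx * dx + dy * dy <= 1
    # clip to the band
    up <- matrix(upper[cols], length(rows), length(cols), byrow = TRUE)
    lo <- matrix(lower[cols], length(rows), length(cols), byrow = TRUE)
    rr <- matrix(rows, length(rows), length(cols))
    inside <- inside & rr >= up & rr < lo
    mask[rows, cols] <- mask[rows, cols] | inside
    frac <- sum(mask) / band_px
  }
  mask
}

#' Generate a synthetic radial scan set with ground truth
#'
#' Builds one B-scan per radial angle: retina band with a foveal surface dip,
#' a 4 px hyperreflective RPE band, a choroid band between smooth undulating
#' boundaries filled with stroma and dark elliptical luminal blobs placed
#' until the target luminal fraction is reached, then a per-column linear
#' tilt shift and multiplicative gamma speckle, quantized to the declared
#' bit depth. All truth (RPE / upper / lower curves, lumen masks, tilt
#' shifts) is recorded in post-tilt coordinates.
#'
#' @param params A [phantom_params()].
#' @return List with elements `set` (a [radial_scan_set()]) and `truth`
#'   (class `phantom_truth`: per-scan `rpe`, `upper`, `lower` curves, logical
#'   `lumen` masks, integer `tilt_shift`, plus the realized global
#'   `luminal_fraction`).
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  g <- params$geometry
  R <- g$axial_px; C <- g$n_alines
  px <- mm_per_px(g)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)

  mean_th_px <- params$mean_choroid_thickness_mm / px[["axial"]]
  und_px <- params$thickness_undulation_mm / px[["axial"]]
  rpe_band_px <- 4L
  rpe_base <- round(0.40 * R)
  max_tilt_shift <- ceiling(tan(params$tilt_deg * pi / 180) * C / 2)
  if (rpe_base - max_tilt_shift < 8L ||
      rpe_base + rpe_band_px + mean_th_px + und_px + max_tilt_shift > R - 4L)
    stop("generate_phantom: geometry too shallow for requested tilt/thickness")

  bscans <- vector("list", g$n_radials)
  truth <- list(rpe = vector("list", g$n_radials),
                upper = vector("list", g$n_radials),
                lower = vector("list", g$n_radials),
                lumen = vector("list", g$n_radials),
                tilt_shift = vector("list", g$n_radials))
  lum_px <- 0; band_px <- 0
  for (kk in seq_len(g$n_radials)) {
    rpe_top <- round(rpe_base + smooth_undulation(C, und_px / 2))
    upper <- rpe_top + rpe_band_px                       # first choroid row
    thick <- round(mean_th_px + smooth_undulation(C, und_px))
    thick <- pmax(thick, 0L)
    lower <- upper + thick                               # first row below band

    # retina band with a foveal dip of the inner surface
    surf <- round(rpe_base - 0.18 * R +
                  0.06 * R * exp(-((seq_len(C) - params$fovea_col) / (0.04 * C))^2))
    surf <- pmax(surf, 2L)

    lev <- matrix(params$background_level, R, C)
    ridx <- seq_len(R)
    for (cc in seq_len(C)) {
      lev[ridx >= surf[cc] & ridx < rpe_top[cc], cc] <- params$retina_level
      lev[ridx >= rpe_top[cc] & ridx < upper[cc], cc] <- params$rpe_level
      lev[ridx >= upper[cc] & ridx < lower[cc], cc] <- params$stroma_level
    }
    lumen <- place_blobs(R, C, upper, lower, params$target_luminal_fraction,
                         params$blob_radius_px_range)
    lev[lumen] <- params$lumen_level

    # linear tilt as per-column integer vertical shift
    tilt <- stats::runif(1, -params$tilt_deg, params$tilt_deg)
    shift <- as.integer(round(tan(tilt * pi / 180) * (seq_len(C) - C / 2)))
    lev <- apply_column_shift(lev, shift, fill = params$background_level)
    lumen <- apply_column_shift(lumen, shift, fill = FALSE) > 0

    img <- if (is.finite(params$speckle_looks)) {
      lev * matrix(stats::rgamma(R * C, shape = params$speckle_looks,
                                 rate = params$speckle_looks), R, C)
    } else lev
    mx <- 2^params$bit_depth - 1
    img <- pmin(pmax(round(img), 0), mx)

    bscans[[kk]] <- img
    truth$rpe[[kk]] <- rpe_top + shift + (rpe_band_px - 1) / 2  # band centre
    truth$upper[[kk]] <- upper + shift
    truth$lower[[kk]] <- lower + shift
    truth$lumen[[kk]] <- lumen
    truth$tilt_shift[[kk]] <- shift
    lum_px <- lum_px + sum(lumen)
    band_px <- band_px + sum(thick)
  }
  truth$luminal_fraction <- lum_px / band_px
  class(truth) <- "phantom_truth"
  set <- radial_scan_set(bscans, g, params$subject, params$label,
                         fovea_col = params$fovea_col,
                         bit_depth = params$bit_depth)
  list(set = set, truth = truth)
}

#' Ground-truth regional volumes of a phantom
#'
#' Integrates the true lumen masks and true boundary curves with the same
#' polar rule as [sector_volumes()], bypassing segmentation and thresholding
#' entirely; serves as the independent quantification oracle for the
#' pipeline.
#'
#' @param truth A `phantom_truth`.
#' @param set The matching [radial_scan_set()].
#' @param rings A [ring_spec()].
#' @param scale Lateral magnification factor (default 1, the phantom's own
#'   frame).
#' @return A `regional_volumes` data.frame.
#' @export
truth_volumes <- function(truth, set, rings = ring_spec(), scale = 1) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(set, "radial_scan_set"))
  g <- set$geometry
  if (length(truth$lumen) != g$n_radials)
    stop("truth_volumes: truth and set geometry mismatch")
  if (any(vapply(truth$lumen, ncol, 1L) != g$n_alines))
    stop("truth_volumes: truth mask width does not match geometry")
  lum <- lapply(truth$lumen, count_mask_columns)
  tot <- lapply(seq_len(g$n_radials), function(kk)
    pmax(truth$lower[[kk]] - truth$upper[[kk]], 0))
  polar_integrate_counts(lum, tot, g, set$fovea_col, scale, rings)
}
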