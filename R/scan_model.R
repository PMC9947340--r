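# Data model for radial OCT scan sets: geometry, subject/session metadata,
# B-scan containers, and lossless directory readers/writers.

#' Scan geometry of a radial SS-OCT acquisition
#'
#' Fixes the pixel-to-millimetre conversion and the radial layout of a scan
#' set. The defaults mirror a macular radial protocol: 18 radial lines at 10
#' degree intervals (tiling the half-circle, since each line carries two
#' semi-meridians), 12 mm scan width with 2048 A-lines, and 3 mm imaged depth.
#'
#' @param n_radials Number of radial B-scans.
#' @param angle_step_deg Angular spacing between radial lines in degrees.
#'   `n_radials * angle_step_deg` must equal 180.
#' @param scan_width_mm Lateral field of view in mm.
#' @param n_alines A-lines (columns) per B-scan.
#' @param axial_depth_mm Imaged depth in mm.
#' @param axial_px Rows per B-scan.
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry()
#' mm_per_px(g)
#' @export
scan_geometry <- function(n_radials = 18L, angle_step_deg = 10,
                          scan_width_mm = 12, n_alines = 2048L,
                          axial_depth_mm = 3, axial_px = 512L) {
  n_radials <- as.integer(n_radials)
  n_alines <- as.integer(n_alines)
  axial_px <- as.integer(axial_px)
  if (n_radials < 1L || n_alines < 2L || axial_px < 2L)
    stop("scan_geometry: pixel counts must be positive (n_alines, axial_px >= 2)")
  if (!isTRUE(all.equal(n_radials * angle_step_deg, 180)))
    stop("scan_geometry: n_radials * angle_step_deg must equal 180 degrees, got ",
         n_radials * angle_step_deg)
  if (scan_width_mm <= 0 || axial_depth_mm <= 0)
    stop("scan_geometry: physical dimensions must be positive")
  structure(list(n_radials = n_radials,
                 angle_step_deg = as.numeric(angle_step_deg),
                 scan_width_mm = as.numeric(scan_width_mm), n_alines = n_alines,
                 axial_depth_mm = as.numeric(axial_depth_mm), axial_px = axial_px),
            class = "scan_geometry")
}

#' Pixel pitch of a scan geometry
#'
#' @param geometry A [scan_geometry()].
#' @return Named numeric vector `c(lateral = , axial = )`, mm per pixel.
#' @export
mm_per_px <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  c(lateral = geometry$scan_width_mm / geometry$n_alines,
    axial = geometry$axial_depth_mm / geometry$axial_px)
}

#' Subject metadata
#'
#' @param subject_id Opaque subject identifier.
#' @param axial_length_mm Ocular axial length in mm (sanity bound 15-40 mm);
#'   drives the ocular magnification correction.
#' @param age_years Age in years.
#' @return An object of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, axial_length_mm, age_years) {
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    stop("subject_meta: subject_id must be a non-empty string")
  if (!is.finite(axial_length_mm) || axial_length_mm <= 15 || axial_length_mm >= 40)
    stop("subject_meta: axial_length_mm out of sanity bounds (15, 40)")
  if (!is.finite(age_years) || age_years <= 0)
    stop("subject_meta: age_years must be positive")
  structure(list(subject_id = subject_id,
                 axial_length_mm = as.numeric(axial_length_mm),
                 age_years = as.numeric(age_years)),
            class = "subject_meta")
}

#' @rdname session_label
#' @export
cq_conditions <- function() c("control", "hyperglycemia")

#' @rdname session_label
#' @export
cq_timepoints <- function() c("baseline", "dark", "light_30s", "light_2min", "light_5min")

#' Session label: condition and timepoint
#'
#' A session is one acquisition of a subject under one physiological state:
#' `condition` distinguishes the control visit from acute hyperglycemia
#' (oral glucose load), `timepoint` the light-adaptation state (ambient-light
#' baseline, after dark adaptation, and 30 s / 2 min / 5 min after return to
#' ambient light).
#'
#' @param condition One of `cq_conditions()`.
#' @param timepoint One of `cq_timepoints()`.
#' @return An object of class `session_label`.
#' @export
session_label <- function(condition, timepoint) {
  condition <- match.arg(condition, cq_conditions())
  timepoint <- match.arg(timepoint, cq_timepoints())
  structure(list(condition = condition, timepoint = timepoint),
            class = "session_label")
}

#' Radial scan set: one session's B-scans plus metadata
#'
#' Container for one acquisition: an ordered list of B-scan images (numeric
#' matrices, rows = depth with row 1 on the vitreous side, columns = A-lines),
#' one per radial angle `(k - 1) * angle_step_deg` for `k = 1..n_radials`,
#' together with geometry, subject, session label, and the fovea-centre
#' column. Radial scans intersect at the fovea, so a single column index is
#' shared by all B-scans.
#'
#' @param bscans List of `n_radials` numeric matrices of dimension
#'   `axial_px x n_alines`, ordered by angle.
#' @param geometry A [scan_geometry()].
#' @param subject A [subject_meta()].
#' @param label A [session_label()].
#' @param fovea_col Fovea-centre column (1-based, in `1..n_alines`).
#' @param bit_depth Intensity quantization, 8 or 16; images hold integer
#'   values in `[0, 2^bit_depth - 1]`.
#' @return An object of class `radial_scan_set`.
#' @export
radial_scan_set <- function(bscans, geometry, subject, label, fovea_col,
                            bit_depth = 8L) {
  stopifnot(inherits(geometry, "scan_geometry"), inherits(subject, "subject_meta"),
            inherits(label, "session_label"))
  if (!is.list(bscans) || length(bscans) != geometry$n_radials)
    stop("radial_scan_set: expected ", geometry$n_radials, " B-scans, got ",
         length(bscans))
  for (k in seq_along(bscans)) {
    b <- bscans[[k]]
    if (!is.matrix(b) || !is.numeric(b))
      stop("radial_scan_set: B-scan ", k, " is not a numeric matrix")
    if (nrow(b) != geometry$axial_px || ncol(b) != geometry$n_alines)
      stop("radial_scan_set: B-scan ", k, " has dimensions ", nrow(b), "x",
           ncol(b), ", geometry declares ", geometry$axial_px, "x",
           geometry$n_alines)
    if (any(b < 0)) stop("radial_scan_set: negative intensities in B-scan ", k)
  }
  fovea_col <- as.integer(fovea_col)
  if (fovea_col < 1L || fovea_col > geometry$n_alines)
    stop("radial_scan_set: fovea_col out of range 1..", geometry$n_alines)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stop("radial_scan_set: bit_depth must be 8 or 16")
  structure(list(bscans = bscans,
                 angles_deg = (seq_len(geometry$n_radials) - 1) * geometry$angle_step_deg,
                 geometry = geometry, subject = subject, label = label,
                 fovea_col = fovea_col, bit_depth = bit_depth),
            class = "radial_scan_set")
}

#' @export
print.radial_scan_set <- function(x, ...) {
  cat("Radial SS-OCT scan set\n")
  cat(sprintf("  subject %s (AL %.2f mm, age %.1f y), %s / %s\n",
              x$subject$subject_id, x$subject$axial_length_mm,
              x$subject$age_years, x$label$condition, x$label$timepoint))
  cat(sprintf("  %d radial B-scans at %g deg steps, %d x %d px (%g x %g mm), fovea col %d\n",
              x$geometry$n_radials, x$geometry$angle_step_deg,
              x$geometry$axial_px, x$geometry$n_alines,
              x$geometry$axial_depth_mm, x$geometry$scan_width_mm, x$fovea_col))
  invisible(x)
}

scale_max <- function(bit_depth) 2^bit_depth - 1

#' Save a radial scan set to a session directory
#'
#' Writes one grayscale image per radial (`bscan_01.tif`, ...) plus a
#' `session.json` sidecar carrying geometry, subject, label, fovea column and
#' bit depth. The round trip through [load_radial_set()] is lossless
#' (bit-exact intensities, exact metadata).
#'
#' @param set A [radial_scan_set()].
#' @param path Destination directory.
#' @param format `"tiff"` (8 or 16 bit) or `"png"` (8 bit only).
#' @param overwrite Refuse to write into an existing non-empty directory
#'   unless `TRUE`.
#' @return `path`, invisibly.
#' @export
save_radial_set <- function(set, path, format = c("tiff", "png"),
                            overwrite = FALSE) {
  stopifnot(inherits(set, "radial_scan_set"))
  format <- match.arg(format)
  if (format == "png" && set$bit_depth != 8L)
    stop("save_radial_set: png output supports bit_depth 8 only")
  if (dir.exists(path) && length(dir(path)) > 0L && !overwrite)
    stop("save_radial_set: destination exists and is not empty; use overwrite = TRUE")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("save_radial_set: cannot create directory ", path)
  ext <- if (format == "tiff") "tif" else "png"
  mx <- scale_max(set$bit_depth)
  for (k in seq_along(set$bscans)) {
    img <- set$bscans[[k]] / mx
    f <- file.path(path, sprintf("bscan_%02d.%s", k, ext))
    if (format == "tiff") {
      tiff::writeTIFF(img, f, bits.per.sample = set$bit_depth)
    } else {
      png::writePNG(img, f)
    }
  }
  sidecar <- list(
    geometry = unclass(set$geometry),
    subject = unclass(set$subject),
    label = unclass(set$label),
    fovea_col = set$fovea_col,
    bit_depth = set$bit_depth,
    image_format = format
  )
  jsonlite::write_json(sidecar, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a radial scan set from a session directory
#'
#' Inverse of [save_radial_set()]; validates all container invariants
#' (B-scan count and dimensions against the declared geometry, fovea column
#' range).
#'
#' @param path Session directory containing `bscan_XX.{tif,png}` images and
#'   `session.json`.
#' @return A validated [radial_scan_set()].
#' @export
load_radial_set <- function(path) {
  sidecar_path <- file.path(path, "session.json")
  if (!file.exists(sidecar_path))
    stop("load_radial_set: missing session.json sidecar in ", path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (key in c("geometry", "subject", "label", "fovea_col", "bit_depth"))
    if (is.null(sc[[key]]))
      stop("load_radial_set: sidecar missing field '", key, "'")
  geometry <- do.call(scan_geometry, as.list(sc$geometry))
  subject <- do.call(subject_meta, as.list(sc$subject))
  label <- do.call(session_label, as.list(sc$label))
  format <- if (is.null(sc$image_format)) "tiff" else sc$image_format
  ext <- if (format == "tiff") "tif" else "png"
  mx <- scale_max(as.integer(sc$bit_depth))
  bscans <- vector("list", geometry$n_radials)
  for (k in seq_len(geometry$n_radials)) {
    f <- file.path(path, sprintf("bscan_%02d.%s", k, ext))
    if (!file.exists(f))
      stop("load_radial_set: missing image for radial ", k, ": ", basename(f))
    img <- if (format == "tiff") tiff::readTIFF(f) else png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # collapse grayscale-as-RGB
    bscans[[k]] <- round(img * mx)
  }
  radial_scan_set(bscans, geometry, subject, label,
                  fovea_col = sc$fovea_col, bit_depth = sc$bit_depth)
}
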