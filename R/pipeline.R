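# End-to-end orchestration: RPE detection -> flattening -> choroid
# segmentation -> Niblack binarization -> magnification-corrected polar
# volumetrics; cohort simulation and CSV reporting.

#' Quantify one radial scan session
#'
#' Runs the full analysis chain on every B-scan of a session: RPE detection,
#' flattening on the RPE reflection, choroid boundary delineation (or
#' externally supplied boundaries), Niblack lumen/stroma binarization, and
#' polar integration into regional volumes with ocular magnification
#' correction from the subject's axial length.
#'
#' @param set A [radial_scan_set()].
#' @param niblack A [niblack_params()].
#' @param rings A [ring_spec()].
#' @param reference_al_mm Reference axial length for
#'   [bennett_lateral_scale()].
#' @param boundaries Optional list of `choroid_segmentation` objects (one
#'   per radial, in post-flattening coordinates) substituting the built-in
#'   boundary search.
#' @param keep_masks Keep per-scan masks and segmentations in the result
#'   (memory-heavy for large geometries).
#' @return Object of class `cvi_quantification`: `volumes` (a
#'   `regional_volumes` data.frame), `scale`, `subject`, `label`, and, when
#'   `keep_masks`, `segmentations` and `binarized`.
#' @export
quantify_session <- function(set, niblack = niblack_params(),
                             rings = ring_spec(), reference_al_mm = 24.46,
                             boundaries = NULL, keep_masks = FALSE) {
  stopifnot(inherits(set, "radial_scan_set"))
  g <- set$geometry
  if (!is.null(boundaries) && length(boundaries) != g$n_radials)
    stop("quantify_session: need one boundary set per radial angle")
  scale <- bennett_lateral_scale(set$subject$axial_length_mm, reference_al_mm)
  bins <- vector("list", g$n_radials)
  segs <- if (keep_masks) vector("list", g$n_radials)
  for (kk in seq_len(g$n_radials)) {
    img <- set$bscans[[kk]]
    rpe <- detect_rpe(img)
    fl <- flatten_bscan(img, rpe)
    if (is.null(boundaries)) {
      rpe_flat <- boundary_curve(rep(fl$target_row, g$n_alines), "rpe",
                                 axial_px = g$axial_px)
      seg <- segment_choroid(fl$image, rpe_flat)
    } else {
      seg <- boundaries[[kk]]
    }
    seg$flatten_shift <- fl$shift
    bins[[kk]] <- binarize_choroid(fl$image, seg, niblack)
    if (keep_masks) segs[[kk]] <- seg
  }
  vols <- sector_volumes(bins, g, set$fovea_col, scale, rings)
  structure(list(volumes = vols, scale = scale, subject = set$subject,
                 label = set$label,
                 segmentations = if (keep_masks) segs,
                 binarized = if (keep_masks) bins),
            class = "cvi_quantification")
}

#' @export
print.cvi_quantification <- function(x, ...) {
  cat(sprintf("Choroidal quantification: subject %s, %s / %s (lateral scale %.4f)\n",
              x$subject$subject_id, x$label$condition, x$label$timepoint, x$scale))
  print(x$volumes)
  invisible(x)
}

#' Flatten a quantification into long-format measurement rows
#'
#' One row per (ring, parameter), with CVI in percent, ready for
#' [measurement_table()].
#'
#' @param q A `cvi_quantification`.
#' @return Data frame in measurement-table layout.
#' @export
as_measurement_rows <- function(q) {
  stopifnot(inherits(q, "cvi_quantification"))
  v <- q$volumes
  do.call(rbind, lapply(seq_len(nrow(v)), function(i) data.frame(
    subject_id = q$subject$subject_id,
    condition = q$label$condition, timepoint = q$label$timepoint,
    ring = v$ring[i],
    parameter = cq_parameters(),
    value = c(v$LV_mm3[i], v$SV_mm3[i], v$TCV_mm3[i], 100 * v$CVI[i]),
    axial_length_mm = q$subject$axial_length_mm,
    age_years = q$subject$age_years)))
}

#' Write / read a volumes CSV
#'
#' One row per (subject, condition, timepoint, ring) with `LV_mm3`,
#' `SV_mm3`, `TCV_mm3` (3 decimals) and `CVI_pct` (2 decimals). A comment
#' header records the seed and config hash for provenance; the reader skips
#' comment lines.
#'
#' @param quants List of `cvi_quantification` objects.
#' @param path Output CSV path.
#' @param seed,config_hash Optional provenance stamped into the header.
#' @return `path` invisibly (writer); data frame (reader).
#' @export
write_volumes_csv <- function(quants, path, seed = NULL, config_hash = NULL) {
  rows <- do.call(rbind, lapply(quants, function(q) {
    v <- q$volumes
    data.frame(subject_id = q$subject$subject_id,
               condition = q$label$condition, timepoint = q$label$timepoint,
               ring = v$ring,
               LV_mm3 = round(v$LV_mm3, 3), SV_mm3 = round(v$SV_mm3, 3),
               TCV_mm3 = round(v$TCV_mm3, 3), CVI_pct = round(100 * v$CVI, 2),
               axial_length_mm = q$subject$axial_length_mm,
               age_years = q$subject$age_years)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# choroquant volumes; seed=%s; config=%s",
                     seed %||% "NA", config_hash %||% "NA"), con)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_volumes_csv
#' @export
read_volumes_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write an adaptation report CSV
#'
#' @param report An `adaptation_report`.
#' @param path Output CSV path.
#' @param seed,config_hash Optional provenance stamped into the header.
#' @return `path` invisibly.
#' @export
write_report_csv <- function(report, path, seed = NULL, config_hash = NULL) {
  stopifnot(inherits(report, "adaptation_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# choroquant report; alpha=%s; seed=%s; config=%s",
                     attr(report, "alpha"), seed %||% "NA", config_hash %||% "NA"),
             con)
  utils::write.csv(as.data.frame(report), con, row.names = FALSE)
  invisible(path)
}

#' Simulate and analyse a full adaptation study at the image level
#'
#' For each subject, condition and timepoint a phantom session is generated
#' (subject axial length and age drawn from a healthy-myopic cohort
#' distribution), quantified through the full image pipeline, and the
#' resulting measurement table is analysed into the adaptation difference
#' report. Condition-by-timepoint effects enter through the phantom's true
#' luminal fraction and choroid thickness.
#'
#' @param n_subjects Number of subjects.
#' @param geometry Scan geometry for the phantoms (the validation default is
#'   a reduced 512 x 192 px frame of the same 12 x 3 mm field).
#' @param base_luminal_fraction True baseline luminal fraction.
#' @param base_thickness_mm True baseline choroid thickness.
#' @param cvi_effects,thickness_effects Named numeric vectors over
#'   timepoints: additive shifts (fraction / mm) applied to the
#'   hyperglycemia condition at that timepoint.
#' @param speckle_looks Phantom speckle severity.
#' @param niblack,rings,reference_al_mm Analysis settings.
#' @param alpha Significance level of the report.
#' @param seed Integer RNG seed; the run is fully deterministic given the
#'   seed and settings.
#' @return List of class `cq_study`: `table` (measurement table), `report`
#'   (adaptation report), `quants` (list of quantifications), `seed`.
#' @export
run_study <- function(n_subjects = 4L,
                      geometry = scan_geometry(n_alines = 512L, axial_px = 192L),
                      base_luminal_fraction = 0.59,
                      base_thickness_mm = 0.30,
                      cvi_effects = c(dark = 0), thickness_effects = c(dark = 0),
                      speckle_looks = 4, niblack = niblack_params(),
                      rings = ring_spec(), reference_al_mm = 24.46,
                      alpha = 0.05, seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  al <- stats::rnorm(n_subjects, 25.47, 1.16)
  al <- pmin(pmax(al, 20), 30)
  age <- pmax(stats::rnorm(n_subjects, 25.29, 1.91), 18)
  quants <- list()
  for (i in seq_len(n_subjects)) {
    subj <- subject_meta(sprintf("S%02d", i), al[i], age[i])
    for (cond in cq_conditions()) for (tp in cq_timepoints()) {
      frac <- base_luminal_fraction
      th <- base_thickness_mm
      if (cond == "hyperglycemia") {
        if (tp %in% names(cvi_effects)) frac <- frac + cvi_effects[[tp]]
        if (tp %in% names(thickness_effects)) th <- th + thickness_effects[[tp]]
      }
      pp <- phantom_params(geometry = geometry,
                           mean_choroid_thickness_mm = th,
                           target_luminal_fraction = frac,
                           speckle_looks = speckle_looks,
                           seed = sample.int(.Machine$integer.max, 1L),
                           subject = subj, label = session_label(cond, tp))
      ph <- generate_phantom(pp)
      quants[[length(quants) + 1L]] <-
        quantify_session(ph$set, niblack, rings, reference_al_mm)
    }
  }
  table <- measurement_table(do.call(rbind, lapply(quants, as_measurement_rows)))
  report <- build_report(table, alpha = alpha)
  structure(list(table = table, report = report, quants = quants, seed = seed),
            class = "cq_study")
}

#' @export
print.cq_study <- function(x, ...) {
  cat("Simulated adaptation study (seed ", x$seed, ", ",
      length(unique(x$table$subject_id)), " subjects)\n", sep = "")
  print(x$report)
  invisible(x)
}
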