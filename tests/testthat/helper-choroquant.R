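# Shared fixtures: all test data are generated in code at run time.

# Reduced validation geometry: same 12 x 3 mm field as the acquisition
# default, at 512 A-lines x 192 rows so phantom-based tests stay fast.
test_geometry <- function(n_alines = 512L, axial_px = 192L,
                          n_radials = 18L, angle_step_deg = 10)
  scan_geometry(n_radials = n_radials, angle_step_deg = angle_step_deg,
                n_alines = n_alines, axial_px = axial_px)

tiny_geometry <- function()
  scan_geometry(n_radials = 6L, angle_step_deg = 30, n_alines = 128L,
                axial_px = 96L)

# Expensive phantoms reused across test files.
.phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(key, params) {
  if (is.null(.phantom_cache[[key]]))
    assign(key, generate_phantom(params), envir = .phantom_cache)
  .phantom_cache[[key]]
}

std_phantom <- function(speckle_looks = 4)
  cached_phantom(paste0("std_", speckle_looks),
                 phantom_params(geometry = test_geometry(), seed = 7,
                                speckle_looks = speckle_looks))

# Brute-force Niblack oracle: per-pixel double loop over the clipped window,
# windowed sums accumulated directly.
naive_niblack <- function(img, radius, k) {
  R <- nrow(img); C <- ncol(img)
  out <- matrix(0, R, C)
  for (i in seq_len(R)) for (j in seq_len(C)) {
    w <- as.double(img[max(1L, i - radius):min(R, i + radius),
                       max(1L, j - radius):min(C, j + radius)])
    n <- length(w)
    m <- sum(w) / n
    out[i, j] <- m + k * sqrt(pmax(sum(w * w) / n - m * m, 0))
  }
  out
}

# Ground truth describing a uniform all-stroma choroid band of the given
# thickness, with zero lumen, plus a matching (blank-image) scan set.
uniform_truth <- function(geometry, thickness_mm = 0.3, upper_row = NULL) {
  R <- geometry$axial_px; C <- geometry$n_alines
  ax <- mm_per_px(geometry)[["axial"]]
  if (is.null(upper_row)) upper_row <- round(0.4 * R)
  upper <- rep(upper_row, C)
  lower <- upper + thickness_mm / ax
  truth <- structure(list(
    rpe = rep(list(upper - 2.5), geometry$n_radials),
    upper = rep(list(upper), geometry$n_radials),
    lower = rep(list(lower), geometry$n_radials),
    lumen = rep(list(matrix(FALSE, R, C)), geometry$n_radials),
    tilt_shift = rep(list(integer(C)), geometry$n_radials)),
    class = "phantom_truth")
  set <- radial_scan_set(rep(list(matrix(0, R, C)), geometry$n_radials),
                         geometry, subject_meta("uniform", 24.46, 25),
                         session_label("control", "baseline"),
                         fovea_col = C %/% 2L + 1L)
  list(truth = truth, set = set)
}

# Run the segmentation chain on one B-scan and return curves plus the
# truth mapped into the flattened frame.
segment_one <- function(ph, kk) {
  g <- ph$set$geometry
  img <- ph$set$bscans[[kk]]
  rpe <- detect_rpe(img)
  fl <- flatten_bscan(img, rpe)
  rpe_flat <- boundary_curve(rep(fl$target_row, g$n_alines), "rpe",
                             axial_px = g$axial_px)
  seg <- segment_choroid(fl$image, rpe_flat)
  list(rpe = rpe, flat = fl, seg = seg,
       truth_upper = ph$truth$upper[[kk]] + fl$shift,
       truth_lower = ph$truth$lower[[kk]] + fl$shift,
       truth_rpe = ph$truth$rpe[[kk]])
}

# Minimal hand-built measurement table (one parameter/ring) for exercising
# the difference bookkeeping.
toy_table <- function(values) {
  # values: named list cond.tp -> numeric vector over subjects
  subj <- sprintf("S%d", seq_along(values[[1]]))
  rows <- do.call(rbind, lapply(names(values), function(key) {
    parts <- strsplit(key, "\\.")[[1]]
    data.frame(subject_id = subj, condition = parts[1], timepoint = parts[2],
               ring = "0-6", parameter = "CVI", value = values[[key]],
               axial_length_mm = 24 + seq_along(subj) * 0.3,
               age_years = 25 + seq_along(subj))
  }))
  measurement_table(rows)
}
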