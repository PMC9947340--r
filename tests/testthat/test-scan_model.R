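test_that("scan geometry enforces the radial tiling and yields correct pixel pitch", {
  g <- scan_geometry()
  expect_equal(g$n_radials * g$angle_step_deg, 180)
  px <- mm_per_px(g)
  expect_equal(px[["lateral"]], 12 / 2048)
  expect_equal(px[["axial"]], 3 / 512)
  # inverse proportionality to pixel counts
  px2 <- mm_per_px(scan_geometry(n_alines = 4096L))
  expect_equal(px2[["lateral"]], px[["lateral"]] / 2)
  expect_gt(min(px), 0)
  expect_error(scan_geometry(n_radials = 12L, angle_step_deg = 10),
               "must equal 180")
  expect_error(scan_geometry(scan_width_mm = -1), "positive")
})

test_that("subject and session metadata are validated", {
  expect_error(subject_meta("s", 14, 25), "sanity bounds")
  expect_error(subject_meta("", 24, 25), "non-empty")
  expect_error(session_label("control", "noon"))
  lbl <- session_label("hyperglycemia", "light_2min")
  expect_equal(lbl$timepoint, "light_2min")
})

test_that("radial scan set container checks dimensions, count and fovea", {
  g <- tiny_geometry()
  mk <- function(n = g$n_radials, nr = g$axial_px, nc = g$n_alines)
    rep(list(matrix(0, nr, nc)), n)
  sm <- subject_meta("s1", 24.46, 25)
  lb <- session_label("control", "baseline")
  expect_s3_class(radial_scan_set(mk(), g, sm, lb, 64L), "radial_scan_set")
  expect_error(radial_scan_set(mk(n = 5L), g, sm, lb, 64L), "expected 6 B-scans")
  expect_error(radial_scan_set(mk(nc = 64L), g, sm, lb, 64L), "dimensions")
  expect_error(radial_scan_set(mk(), g, sm, lb, 0L), "fovea_col")
  expect_error(radial_scan_set(mk(), g, sm, lb, 64L, bit_depth = 12L), "bit_depth")
})

test_that("save/load round trip is lossless for tiff (8/16 bit) and png", {
  g <- tiny_geometry()
  for (spec in list(list(bits = 8L, fmt = "tiff"), list(bits = 16L, fmt = "tiff"),
                    list(bits = 8L, fmt = "png"))) {
    ph <- generate_phantom(phantom_params(geometry = g, seed = 5,
                                          bit_depth = spec$bits,
                                          blob_radius_px_range = c(2, 4)))
    d <- withr::local_tempdir()
    save_radial_set(ph$set, d, format = spec$fmt, overwrite = TRUE)
    s2 <- load_radial_set(d)
    expect_identical(s2$bscans, ph$set$bscans)
    expect_identical(unclass(s2$geometry), unclass(ph$set$geometry))
    expect_identical(unclass(s2$subject), unclass(ph$set$subject))
    expect_identical(unclass(s2$label), unclass(ph$set$label))
    expect_identical(s2$fovea_col, ph$set$fovea_col)
    expect_identical(s2$bit_depth, ph$set$bit_depth)
  }
})

test_that("loader rejects inconsistent or incomplete session directories", {
  g <- tiny_geometry()
  ph <- generate_phantom(phantom_params(geometry = g, seed = 5,
                                        blob_radius_px_range = c(2, 4)))
  d <- withr::local_tempdir()
  save_radial_set(ph$set, d, overwrite = TRUE)
  # refuse to clobber an existing session without the force flag
  expect_error(save_radial_set(ph$set, d), "overwrite")

  # sidecar declaring a different width than the images
  sc <- jsonlite::read_json(file.path(d, "session.json"), simplifyVector = TRUE)
  sc$geometry$n_alines <- 64L
  sc$geometry$scan_width_mm <- 12
  jsonlite::write_json(sc, file.path(d, "session.json"), auto_unbox = TRUE)
  expect_error(load_radial_set(d), "dimensions")

  # missing image for one radial
  d2 <- withr::local_tempdir()
  save_radial_set(ph$set, d2, overwrite = TRUE)
  file.remove(file.path(d2, "bscan_03.tif"))
  expect_error(load_radial_set(d2), "missing image")

  # missing sidecar entirely
  expect_error(load_radial_set(withr::local_tempdir()), "session.json")
})
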