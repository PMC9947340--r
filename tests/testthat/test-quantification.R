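test_that("Bennett magnification ratio behaves as a relative lateral scale", {
  expect_equal(bennett_lateral_scale(24.46), 1)
  expect_equal(bennett_lateral_scale(25.47), 23.65 / 22.64)
  al <- seq(20, 30, by = 0.5)
  expect_true(all(diff(vapply(al, bennett_lateral_scale, numeric(1))) > 0))
  expect_error(bennett_lateral_scale(1.5), "exceed 1.82")
})

test_that("A-line radii are centred on the fovea and linear in the scale", {
  g <- scan_geometry()
  r <- aline_radii(g, fovea_col = 1025L)
  expect_equal(r[1025], 0)
  expect_equal(r[1025 + 512], 512 * 12 / 2048)  # 3 mm
  expect_equal(aline_radii(g, 1025L, scale = 2), 2 * r)
})

test_that("ring specification validates diameters and partitions the disc", {
  rs <- ring_spec()
  expect_equal(rs$ring, c("0-3", "3-6", "0-6"))
  expect_error(ring_spec(list(c(3, 3))), "inner < outer")
  expect_error(ring_spec(list(c(-1, 3))), "inner < outer")
})

test_that("CVI is the luminal fraction of total volume with NA when undefined", {
  expect_equal(cvi(15.34, 26.08), 15.34 / 26.08)  # 58.82% from summed volumes
  expect_equal(cvi(0, 5), 0)
  expect_equal(cvi(5, 5), 1)
  expect_true(is.na(cvi(0, 0)))
  expect_error(cvi(6, 5), "LV <= TCV")
})

test_that("sector volumes from truth masks equal the truth oracle exactly", {
  ph <- std_phantom(4)
  g <- ph$set$geometry
  bins <- lapply(seq_len(g$n_radials), function(kk) {
    roi <- choroquant:::roi_mask_from_curves(ph$truth$upper[[kk]],
                                             ph$truth$lower[[kk]], g$axial_px)
    lum <- ph$truth$lumen[[kk]] & roi
    structure(list(lumen_mask = lum, stroma_mask = roi & !lum, roi_mask = roi),
              class = "binarized_choroid")
  })
  sv <- sector_volumes(bins, g, ph$set$fovea_col)
  tv <- truth_volumes(ph$truth, ph$set)
  expect_equal(sv$LV_mm3, tv$LV_mm3, tolerance = 1e-12)
  expect_equal(sv$TCV_mm3, tv$TCV_mm3, tolerance = 1e-12)
})

test_that("volumes conserve the partition, add over rings, and ignore angular relabeling", {
  ph <- std_phantom(4)
  g <- ph$set$geometry
  q <- quantify_session(ph$set)
  v <- q$volumes
  expect_lt(max(abs(v$LV_mm3 + v$SV_mm3 - v$TCV_mm3)), 1e-9)
  expect_lt(max(abs(v$LV_mm3[1] + v$LV_mm3[2] - v$LV_mm3[3])), 1e-12)
  expect_lt(max(abs(v$TCV_mm3[1] + v$TCV_mm3[2] - v$TCV_mm3[3])), 1e-12)

  # rotating the blob field by one angular step = cyclic relabeling of the
  # B-scans; the polar rule weighs every semi-meridian equally
  rot <- ph$set
  rot$bscans <- ph$set$bscans[c(2:g$n_radials, 1)]
  q2 <- quantify_session(rot)
  expect_lt(max(abs(q2$volumes$CVI - v$CVI)), 0.01)
})

test_that("uniform all-stroma choroid reproduces the analytic disc volume", {
  u <- uniform_truth(test_geometry(), 0.3)
  tv <- truth_volumes(u$truth, u$set)
  expect_lt(abs(tv$TCV_mm3[3] / (pi * 9 * 0.3) - 1), 0.01)
  expect_lt(abs(tv$TCV_mm3[3] / (pi * (3^2 - 1.5^2) * 0.3 + pi * 1.5^2 * 0.3) - 1), 0.01)
  expect_equal(tv$TCV_mm3[1] + tv$TCV_mm3[2], tv$TCV_mm3[3], tolerance = 1e-12)
  expect_equal(tv$CVI, rep(0, 3))
})

test_that("undefined CVI is reported missing when a ring is empty", {
  g <- tiny_geometry()
  u <- uniform_truth(g, 0.05)
  # ring entirely outside the scanned field: TCV = 0 there
  rs <- ring_spec(list(c(0, 3), c(20, 24)))
  tv <- truth_volumes(u$truth, u$set, rings = rs)
  expect_true(is.na(tv$CVI[2]))
  expect_false(is.na(tv$CVI[1]))
})
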