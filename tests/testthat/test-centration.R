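test_that("calibration reproduces the WTW magnification worked example", {
  # limbus 214.23 px across for WTW 10.28 mm -> 0.047985 mm/px
  limbus <- fit_ellipse(iclcentr:::.ellipse_points(160, 160, 214.23 / 2, 100, n = 48))
  cal <- calibrate(limbus, wtw_mm = 10.28)
  expect_equal(cal$mm_per_px, 10.28 / 214.23, tolerance = 1e-6)
  expect_equal(cal$mm_per_px, 0.04799, tolerance = 1e-4)
  # a 7.5 px hole at that scale is the physical 360-um hole
  expect_equal(7.5 * cal$mm_per_px, 0.360, tolerance = 2e-3)
})

test_that("identity scale and out-of-range WTW behave as specified", {
  limbus <- fit_ellipse(iclcentr:::.ellipse_points(100, 100, 10.28 / 2, 5, n = 32))
  cal <- calibrate(limbus, wtw_mm = 10.28) # limbus px numerically equals WTW mm
  expect_equal(cal$mm_per_px, 1, tolerance = 1e-9)
  expect_error(calibrate(limbus, wtw_mm = 8), class = "icl_input_error")
  expect_error(calibrate(limbus, wtw_mm = 15), class = "icl_input_error")
})

fake_seg <- function(lim_c, pup_c, hole_c) {
  ell <- function(ctr, ax) {
    structure(list(center = ctr, semi_axes = ax, rotation = 0,
      rms_residual = 0, n_support = 99, conic = NULL), class = "icl_ellipse")
  }
  structure(list(
    limbus = ell(lim_c, c(107, 101)), pupil = ell(pup_c, c(26, 25)),
    hole = ell(hole_c, c(3.75, 3.75)),
    flags = c(pupil_in_limbus = TRUE, hole_in_pupil = TRUE)
  ), class = "icl_segmentation")
}

test_that("anatomic-frame conversion handles origin, y-flip and OS mirroring", {
  limbus <- fit_ellipse(iclcentr:::.ellipse_points(160, 160, 107, 101, n = 48))
  cal <- list(mm_per_px = 0.048, wtw_mm = 10.28, cornea_h_px = 214,
    hole_px = 7.5)
  class(cal) <- "icl_calibration"
  # coincident centres -> (0, 0)
  seg <- fake_seg(c(160, 160), c(160, 160), c(160, 160))
  rec <- to_anatomic_frame(seg, cal, "OD")
  expect_equal(rec$cx_hole_mm, 0)
  expect_equal(rec$cy_hole_mm, 0)
  # raster offset (+d, 0): OS result is the x-negation of the OD result
  seg2 <- fake_seg(c(160, 160), c(160, 160), c(170, 160))
  od <- to_anatomic_frame(seg2, cal, "OD")
  os <- to_anatomic_frame(seg2, cal, "OS")
  expect_equal(os$cx_hole_mm, -od$cx_hole_mm)
  expect_equal(os$cy_hole_mm, od$cy_hole_mm)
  expect_equal(od$cx_hole_mm, 10 * 0.048)
  # raster y grows downward; superior offsets must come out positive
  seg3 <- fake_seg(c(160, 160), c(160, 150), c(160, 160))
  expect_gt(to_anatomic_frame(seg3, cal, "OD")$cy_pupil_mm, 0)
})

test_that("failed quality flags propagate as detection errors", {
  seg <- fake_seg(c(160, 160), c(160, 160), c(160, 160))
  seg$flags[["hole_in_pupil"]] <- FALSE
  cal <- structure(list(mm_per_px = 0.048, wtw_mm = 10.28,
    cornea_h_px = 214, hole_px = 7.5), class = "icl_calibration")
  expect_error(to_anatomic_frame(seg, cal, "OD"), class = "icl_detect_error")
})

test_that("distances follow D = sqrt(X^2 + Y^2) with consistent components", {
  rec <- compute_distances(tibble::tibble(
    cx_hole_mm = c(0, 0.3, 0.16), cy_hole_mm = c(0, 0.4, 0.30),
    cx_pupil_mm = c(0, 0, 0), cy_pupil_mm = c(0, 0, 0)
  ))
  expect_equal(rec$d_hc_mm, c(0, 0.5, sqrt(0.16^2 + 0.30^2)))
  expect_equal(rec$d_hc_mm[3], 0.3400, tolerance = 1e-4)
  expect_equal(rec$d_hp_mm, rec$d_hc_mm) # pupil at origin
  expect_equal(rec$d_pc_mm, c(0, 0, 0))
  expect_equal(rec$dhx_mm, abs(rec$cx_hole_mm))
})

test_that("distance invariants hold on random records", {
  set.seed(99)
  rec <- compute_distances(tibble::tibble(
    cx_hole_mm = rnorm(200, 0, 0.3), cy_hole_mm = rnorm(200, 0, 0.3),
    cx_pupil_mm = rnorm(200, 0, 0.3), cy_pupil_mm = rnorm(200, 0, 0.3)
  ))
  expect_equal(rec$d_hc_mm, sqrt(rec$cx_hole_mm^2 + rec$cy_hole_mm^2),
    tolerance = 1e-12)
  expect_true(all(rec$d_hp_mm <= rec$d_hc_mm + rec$d_pc_mm + 1e-12))
  expect_true(all(rec$dhx_mm == abs(rec$cx_hole_mm)))
  # collinear fixture: triangle inequality becomes equality
  col <- compute_distances(tibble::tibble(
    cx_hole_mm = 0.4, cy_hole_mm = 0.4, cx_pupil_mm = -0.2, cy_pupil_mm = -0.2
  ))
  expect_equal(col$d_hp_mm, col$d_hc_mm + col$d_pc_mm, tolerance = 1e-12)
})

test_that("quadrant classification reads signs with the boundary tie-break", {
  q <- classify_quadrant(c(0.1, -0.1, 0, 0.2), c(0.2, -0.2, 0, -0.1))
  expect_equal(q$quadrant, c("superior-nasal", "inferior-temporal",
    "superior-nasal", "inferior-nasal"))
  expect_equal(q$boundary, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("end-to-end measurement recovers a known offset on a clean render", {
  eye <- make_test_eye(hole_x = 0.10, hole_y = 0.30)
  r <- render_eye(eye, render_config(noise_sd = 0), seed = 21)
  rec <- measure_eye(r$image, wtw_mm = eye$wtw_mm, laterality = "OD")
  expect_lt(abs(rec$cx_hole_mm - 0.10), 0.02)
  expect_lt(abs(rec$cy_hole_mm - 0.30), 0.02)
})

test_that("measurements are scale invariant between 24 and 48 um/px", {
  eye <- make_test_eye()
  r48 <- render_eye(eye, render_config(scale_um_per_px = 48, noise_sd = 0), seed = 3)
  r24 <- render_eye(eye, render_config(scale_um_per_px = 24, noise_sd = 0,
    width = 640, height = 640), seed = 3)
  m48 <- measure_eye(r48$image, eye$wtw_mm, "OD", max_pupil_px = 300)
  m24 <- measure_eye(r24$image, eye$wtw_mm, "OD", max_pupil_px = 300)
  for (col in c("cx_hole_mm", "cy_hole_mm", "cx_pupil_mm", "cy_pupil_mm",
                "d_hc_mm", "d_pc_mm", "d_hp_mm")) {
    expect_lt(abs(m48[[col]] - m24[[col]]), 0.02)
  }
})

test_that("measure_cohort joins metadata and drops failing eyes with a message", {
  eyes <- sample_cohort(cohort_params(n_eyes = 3), seed = 41)
  renders <- lapply(seq_len(3), function(i) {
    render_eye(eyes[i, ], render_config(), seed = 41 + i)
  })
  recs <- suppressMessages(measure_cohort(renders, eyes))
  expect_equal(nrow(recs), 3)
  expect_true(all(c("kappa_x_mm", "kappa_y_mm") %in% names(recs)))
  # one blank image fails, others survive
  imgs <- lapply(renders, function(r) r$image)
  names(imgs) <- eyes$eye_id
  imgs[[2]] <- matrix(0.5, 320, 320)
  recs2 <- suppressMessages(measure_cohort(imgs, eyes))
  expect_equal(nrow(recs2), 2)
  expect_length(attr(recs2, "failures"), 1)
  # missing WTW skips the eye with a named-field message
  md <- eyes
  md$wtw_mm[1] <- NA
  expect_message(
    recs3 <- measure_cohort(imgs[1], md),
    "wtw_mm"
  )
  expect_equal(nrow(recs3), 0)
})
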