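test_that("degenerate distributions give identical eyes at the configured means", {
  p <- cohort_params(
    n_eyes = 6,
    hole_x_sd = 0, hole_y_sd = 0, pupil_x_sd = 0, pupil_y_sd = 0,
    hole_p_nasal = 1, hole_p_superior = 1,
    pupil_p_nasal = 1, pupil_p_superior = 1,
    wtw_sd = 0, cornea_v_sd = 0, pupil_dh_sd = 0, pupil_dv_sd = 0,
    kappa_x_sd = 0, kappa_y_sd = 0
  )
  eyes <- sample_cohort(p, seed = 5)
  expect_equal(nrow(eyes), 6)
  expect_true(all(eyes$cx_hole_mm == 0.16))
  expect_true(all(eyes$cy_hole_mm == 0.30))
  expect_true(all(eyes$cx_pupil_mm == 0.28))
  expect_true(all(eyes$cy_pupil_mm == 0.27))
  expect_true(all(eyes$hole_diameter_um == 360))
})

test_that("sampling is bit-identical for a fixed seed and differs across seeds", {
  p <- cohort_params(n_eyes = 50)
  expect_identical(sample_cohort(p, seed = 11), sample_cohort(p, seed = 11))
  expect_false(identical(sample_cohort(p, seed = 11), sample_cohort(p, seed = 12)))
})

test_that("large-sample magnitude moments match the truncated-normal oracle", {
  # wide pupils so the anatomical containment rule never rejects an eye and
  # the closed-form truncated-normal moments apply exactly
  p <- cohort_params(n_eyes = 10000, pupil_dh_mean = 4.5, pupil_dv_mean = 4.3,
    pupil_dh_sd = 0.2, pupil_dv_sd = 0.2)
  eyes <- sample_cohort(p, seed = 31)
  cases <- list(
    list(v = abs(eyes$cx_hole_mm), mu = 0.16, sd = 0.12),
    list(v = abs(eyes$cy_hole_mm), mu = 0.30, sd = 0.19),
    list(v = abs(eyes$cx_pupil_mm), mu = 0.28, sd = 0.19),
    list(v = abs(eyes$cy_pupil_mm), mu = 0.27, sd = 0.14)
  )
  for (cs in cases) {
    m_exp <- truncnorm_mean(cs$mu, cs$sd)
    s_exp <- truncnorm_sd(cs$mu, cs$sd)
    se <- s_exp / sqrt(nrow(eyes))
    expect_lt(abs(mean(cs$v) - m_exp), 3 * se)
    expect_lt(abs(sd(cs$v) - s_exp), 0.05 * s_exp)
  }
  # the hole |x| sample mean sits slightly above 0.16 (truncation shift)
  expect_gt(mean(abs(eyes$cx_hole_mm)), 0.15)
  expect_lt(mean(abs(eyes$cx_hole_mm)), 0.19)
  # at the default pupil sizes the containment rule trims joint extremes;
  # the marginal means may shift from the unconditional values only slightly
  eyes_def <- sample_cohort(cohort_params(n_eyes = 10000), seed = 31)
  expect_lt(abs(mean(abs(eyes_def$cx_pupil_mm)) - truncnorm_mean(0.28, 0.19)), 0.01)
  expect_lt(abs(mean(abs(eyes_def$cy_hole_mm)) - truncnorm_mean(0.30, 0.19)), 0.01)
})

test_that("copula coupling reproduces the target rank correlations", {
  eyes <- sample_cohort(cohort_params(n_eyes = 10000), seed = 77)
  r_x <- cor(abs(eyes$cx_hole_mm), abs(eyes$cx_pupil_mm), method = "spearman")
  r_y <- cor(abs(eyes$cy_hole_mm), abs(eyes$cy_pupil_mm), method = "spearman")
  expect_lt(abs(r_x - 0.57), 0.03)
  expect_lt(abs(r_y - 0.42), 0.03)
})

test_that("every sampled eye satisfies anatomical containment", {
  eyes <- sample_cohort(cohort_params(n_eyes = 2000), seed = 13)
  r_hole <- eyes$hole_diameter_um / 2000
  expect_true(all(abs(eyes$cx_pupil_mm) + eyes$pupil_dh_mm / 2 < eyes$wtw_mm / 2))
  expect_true(all(
    abs(eyes$cy_pupil_mm) + eyes$pupil_dv_mm / 2 < eyes$cornea_vertical_mm / 2
  ))
  expect_true(all(
    ((eyes$cx_hole_mm - eyes$cx_pupil_mm) / (eyes$pupil_dh_mm / 2 - r_hole))^2 +
      ((eyes$cy_hole_mm - eyes$cy_pupil_mm) / (eyes$pupil_dv_mm / 2 - r_hole))^2 < 1
  ))
})

test_that("ground-truth table round-trips through CSV without loss", {
  eyes <- sample_cohort(cohort_params(n_eyes = 20), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  suppressMessages(write_cohort_csv(eyes, path))
  back <- read_cohort_csv(path)
  for (col in names(eyes)) {
    if (is.numeric(eyes[[col]])) {
      expect_lt(max(abs(eyes[[col]] - back[[col]])), 1e-9)
    } else {
      expect_identical(as.character(eyes[[col]]), as.character(back[[col]]))
    }
  }
})

test_that("invalid cohort parameters fail naming the offending field", {
  expect_error(cohort_params(n_eyes = 0), "n_eyes", class = "icl_config_error")
  expect_error(cohort_params(hole_x_sd = -1), "hole_x_sd", class = "icl_config_error")
  expect_error(cohort_params(hole_p_nasal = 1.2), "hole_p_nasal",
    class = "icl_config_error")
  expect_error(cohort_params(rho_x = 2), "rho_x", class = "icl_config_error")
})

test_that("kappa offsets follow the configured rank coupling", {
  eyes <- sample_cohort(cohort_params(n_eyes = 5000), seed = 9)
  hpy <- eyes$cy_hole_mm - eyes$cy_pupil_mm
  r <- cor(eyes$kappa_y_mm, hpy, method = "spearman")
  expect_lt(abs(r - (-0.435)), 0.06)
})
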