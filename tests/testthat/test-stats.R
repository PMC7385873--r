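test_that("percentage arithmetic matches the published table convention", {
  expect_equal(percent(85, 89), 95.51)
  expect_equal(percent(34, 89), 38.20)
  expect_equal(percent(0, 89), 0.00)
  expect_equal(percent(1, 3), 33.33)
  expect_equal(percent(2, 3), 66.67)
  expect_error(percent(1, 0), class = "icl_input_error")
  expect_error(percent(5, 3), class = "icl_input_error")
})

test_that("all-equal pairs give p = 1 with the all-zero flag", {
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_true(w$all_zero)
  expect_equal(w$p_value, 1)
})

test_that("six all-positive differences give the enumerated exact p", {
  a <- c(11, 12, 13, 14, 15, 16)
  b <- a - (1:6)
  w <- wilcoxon_signed_rank(a, b)
  expect_true(w$exact)
  expect_equal(w$statistic, 21)
  expect_equal(w$p_value, 2 / 64)
})

test_that("exact p equals the sign-enumeration oracle for n <= 10, ties included", {
  set.seed(15)
  for (k in 1:20) {
    n <- sample(5:10, 1)
    a <- round(rnorm(n, 0.3, 1), 1) # rounding induces tied |differences|
    b <- round(rnorm(n, 0.0, 1), 1)
    if (all(a == b)) next
    w <- wilcoxon_signed_rank(a, b)
    expect_equal(w$p_value, enum_wilcoxon_p(a, b), tolerance = 1e-12)
  }
})

test_that("exact p matches stats::wilcox.test when there are no ties", {
  set.seed(8)
  for (k in 1:10) {
    a <- rnorm(12)
    b <- rnorm(12)
    w <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(w$statistic, unname(ref$statistic))
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample approximation matches stats::wilcox.test", {
  set.seed(9)
  a <- rnorm(60, 0.2)
  b <- rnorm(60)
  w <- wilcoxon_signed_rank(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_false(w$exact)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("spearman matches monotone limits and the rank-Pearson oracle", {
  x <- 1:8
  expect_equal(spearman_rank(x, x^3)$estimate, 1)
  expect_equal(spearman_rank(x, -x - 5)$estimate, -1)
  # tied fixture: estimate equals Pearson on average ranks
  a <- c(1, 2, 2, 3, 4, 5, 5, 6)
  b <- c(2, 1, 4, 4, 5, 7, 6, 8)
  s <- spearman_rank(a, b)
  expect_equal(s$estimate, stats::cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_equal(s$estimate,
    stats::cor.test(a, b, method = "spearman", exact = FALSE)$estimate,
    tolerance = 1e-12, ignore_attr = TRUE)
  # p from the t approximation
  n <- length(a)
  r <- s$estimate
  expect_equal(s$p_value, 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2),
    tolerance = 1e-12)
  # degenerate ranks flagged
  d <- spearman_rank(rep(1, 6), 1:6)
  expect_true(d$degenerate)
  expect_true(is.na(d$estimate))
})

make_records <- function(n = 20, seed = 1, kappa = TRUE) {
  eyes <- sample_cohort(cohort_params(n_eyes = n), seed = seed)
  rec <- compute_distances(eyes)
  if (!kappa) rec$kappa_x_mm <- rec$kappa_y_mm <- NULL
  rec
}

test_that("cohort summary reproduces hand-computed moments", {
  rec <- compute_distances(tibble::tibble(
    cx_hole_mm = c(0, 0), cy_hole_mm = c(0.2, 0.4),
    cx_pupil_mm = c(0, 0), cy_pupil_mm = c(0, 0)
  ))
  s <- summarize_cohort(rec)
  m <- s$metrics[s$metrics$metric == "d_hc_mm", ]
  expect_equal(m$mean, 0.30)
  expect_equal(m$sd, sqrt(0.02), tolerance = 1e-4)
  expect_false(any(s$wilcoxon$available)) # n < 5: tests unavailable
  # identical records give zero dispersion
  s2 <- summarize_cohort(rec[c(1, 1), ])
  expect_true(all(s2$metrics$sd == 0))
  expect_error(summarize_cohort(rec[0, ]), class = "icl_input_error")
})

test_that("quadrant tables count every eye and percentages total 100", {
  rec <- make_records(n = 89, seed = 2)
  s <- summarize_cohort(rec)
  for (q in s$quadrants) {
    expect_equal(sum(q$count), 89)
    expect_lt(abs(sum(q$percent) - 100), 0.05)
  }
  # permutation invariance of the counts
  s_perm <- summarize_cohort(rec[sample(nrow(rec)), ])
  expect_equal(s_perm$quadrants, s$quadrants)
})

test_that("summary means track the truncated-normal oracle on a large cohort", {
  rec <- make_records(n = 10000, seed = 3)
  s <- summarize_cohort(rec)
  m_dhx <- s$metrics$mean[s$metrics$metric == "dhx_mm"]
  expect_lt(abs(m_dhx - truncnorm_mean(0.16, 0.12)), 0.02)
})

test_that("kappa correlations respect coupling, nulls, and absence", {
  # null coupling: |r| small at n = 200
  p0 <- cohort_params(n_eyes = 200, kappa_rho_x = 0, kappa_rho_y = 0)
  rec0 <- compute_distances(sample_cohort(p0, seed = 4))
  k0 <- kappa_correlations(rec0)
  expect_true(all(abs(k0$r[k0$pair %in% c("K-x ~ DHPx", "K-y ~ DHPy")]) <= 0.2))
  # negative coupling -0.4 on the y pair lands in [-0.6, -0.2]
  p1 <- cohort_params(n_eyes = 200, kappa_rho_y = -0.4)
  rec1 <- compute_distances(sample_cohort(p1, seed = 5))
  k1 <- kappa_correlations(rec1)
  r_y <- k1$r[k1$pair == "K-y ~ DHPy"]
  expect_gte(r_y, -0.6)
  expect_lte(r_y, -0.2)
  # records without kappa columns: flagged-absent table
  k2 <- kappa_correlations(make_records(n = 20, seed = 6, kappa = FALSE))
  expect_true(all(!k2$available))
  expect_true(all(is.na(k2$r)))
})

test_that("tidy and glance return the expected shapes", {
  s <- summarize_cohort(make_records(n = 30, seed = 7))
  td <- generics::tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 7)
  gl <- generics::glance(s)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n, 30)
  expect_true(is.finite(gl$p_dhx_dpx))
})

test_that("p-value formatting follows the reporting convention", {
  expect_equal(format_p(0.0005), "p < 0.001")
  expect_equal(format_p(0.058), "p = 0.058")
  expect_equal(format_p(NA), "p = NA")
})
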