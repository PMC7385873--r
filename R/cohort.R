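#' Cohort-level simulation parameters
#'
#' Bundles the distributional parameters from which synthetic eyes are drawn.
#' Offset vectors (central hole vs corneal centre, pupil centre vs corneal
#' centre) are modelled as an unsigned component magnitude times an
#' independently drawn anatomic sign: magnitudes follow normal distributions
#' truncated at zero, signs are Bernoulli with the configured probability of
#' the nasal (+x) or superior (+y) direction. Hole and pupil magnitudes on the
#' same axis are coupled through a Gaussian copula so the cohort reproduces a
#' target Spearman rank correlation.
#'
#' Defaults reproduce the published 89-eye EVO-ICL cohort: hole offset
#' magnitudes x ~ N(0.16, 0.12^2), y ~ N(0.30, 0.19^2) mm; pupil offset
#' magnitudes x ~ N(0.28, 0.19^2), y ~ N(0.27, 0.14^2) mm; rank coupling 0.57
#' (x) and 0.42 (y); sign probabilities from the printed quadrant counts.
#' White-to-white, corneal vertical and pupil diameters are back-converted
#' from the printed pixel statistics at the 48 um/px hole-fixed scale.
#'
#' Kappa (pupil-offset) metadata are drawn with a configurable rank coupling
#' to the signed hole-minus-pupil components (`kappa_rho_x`, `kappa_rho_y`);
#' set these to 0 for kappa independent of lens position.
#'
#' @param n_eyes Number of eyes to simulate.
#' @param hole_x_mean,hole_x_sd,hole_y_mean,hole_y_sd Moments (mm) of the
#'   untruncated normal behind the hole-to-corneal-centre |x| and |y|.
#' @param pupil_x_mean,pupil_x_sd,pupil_y_mean,pupil_y_sd Same for the
#'   pupil-to-corneal-centre vector.
#' @param hole_p_nasal,hole_p_superior,pupil_p_nasal,pupil_p_superior
#'   Probability that the respective signed component points nasally (+x)
#'   or superiorly (+y).
#' @param rho_x,rho_y Target Spearman correlation between hole and pupil
#'   magnitudes on each axis.
#' @param wtw_mean,wtw_sd White-to-white (horizontal corneal diameter), mm.
#' @param cornea_v_mean,cornea_v_sd Vertical corneal diameter, mm.
#' @param pupil_dh_mean,pupil_dh_sd,pupil_dv_mean,pupil_dv_sd Pupil
#'   horizontal/vertical diameters, mm.
#' @param p_od Probability an eye is a right eye (OD).
#' @param kappa_x_mean,kappa_x_sd,kappa_y_mean,kappa_y_sd Kappa x/y offset
#'   distribution, mm (+x nasal, +y superior).
#' @param kappa_rho_x,kappa_rho_y Target Spearman correlation between kappa
#'   offsets and the signed hole-minus-pupil x/y components.
#' @return A validated list of class `icl_cohort_params`.
#' @export
cohort_params <- function(n_eyes = 89,
                          hole_x_mean = 0.16, hole_x_sd = 0.12,
                          hole_y_mean = 0.30, hole_y_sd = 0.19,
                          pupil_x_mean = 0.28, pupil_x_sd = 0.19,
                          pupil_y_mean = 0.27, pupil_y_sd = 0.14,
                          hole_p_nasal = 44 / 89, hole_p_superior = 85 / 89,
                          pupil_p_nasal = 86 / 89, pupil_p_superior = 88 / 89,
                          rho_x = 0.57, rho_y = 0.42,
                          wtw_mean = 10.28, wtw_sd = 0.70,
                          cornea_v_mean = 9.69, cornea_v_sd = 0.59,
                          pupil_dh_mean = 2.54, pupil_dh_sd = 0.57,
                          pupil_dv_mean = 2.43, pupil_dv_sd = 0.56,
                          p_od = 0.5,
                          kappa_x_mean = 0.15, kappa_x_sd = 0.10,
                          kappa_y_mean = 0.02, kappa_y_sd = 0.10,
                          kappa_rho_x = -0.253, kappa_rho_y = -0.435) {
  p <- as.list(environment())
  .check_param <- function(ok, field, what) {
    if (!isTRUE(ok)) {
      rlang::abort(
        sprintf("invalid cohort parameter `%s`: %s", field, what),
        class = "icl_config_error"
      )
    }
  }
  .check_param(length(p$n_eyes) == 1 && is.finite(p$n_eyes) && p$n_eyes >= 1 &&
    p$n_eyes == round(p$n_eyes), "n_eyes", "must be an integer >= 1")
  for (f in grep("_sd$", names(p), value = TRUE)) {
    .check_param(is.finite(p[[f]]) && p[[f]] >= 0, f, "sd must be >= 0")
  }
  for (f in c("hole_p_nasal", "hole_p_superior", "pupil_p_nasal",
              "pupil_p_superior", "p_od")) {
    .check_param(is.finite(p[[f]]) && p[[f]] >= 0 && p[[f]] <= 1, f,
      "probability must lie in [0, 1]")
  }
  for (f in c("rho_x", "rho_y", "kappa_rho_x", "kappa_rho_y")) {
    .check_param(is.finite(p[[f]]) && abs(p[[f]]) <= 1, f,
      "correlation must lie in [-1, 1]")
  }
  for (f in c("wtw_mean", "cornea_v_mean", "pupil_dh_mean", "pupil_dv_mean")) {
    .check_param(is.finite(p[[f]]) && p[[f]] > 0, f, "must be > 0")
  }
  structure(p, class = "icl_cohort_params")
}

#' @export
print.icl_cohort_params <- function(x, ...) {
  cat(sprintf(
    "<cohort params> n = %d eyes\n  hole |x| ~ N(%.2f, %.2f^2), |y| ~ N(%.2f, %.2f^2) mm (trunc. at 0)\n  pupil |x| ~ N(%.2f, %.2f^2), |y| ~ N(%.2f, %.2f^2) mm\n  rank coupling x = %.2f, y = %.2f; WTW %.2f +/- %.2f mm\n",
    x$n_eyes, x$hole_x_mean, x$hole_x_sd, x$hole_y_mean, x$hole_y_sd,
    x$pupil_x_mean, x$pupil_x_sd, x$pupil_y_mean, x$pupil_y_sd,
    x$rho_x, x$rho_y, x$wtw_mean, x$wtw_sd
  ))
  invisible(x)
}

# quantile of the normal truncated to [0, Inf); degenerate sd -> point mass
.qtruncnorm0 <- function(u, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), length(u)))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + u * (1 - p0), mean, sd)
}

# mean of a normal(mean, sd) truncated at 0 (oracle for distributional tests)
.truncnorm0_mean <- function(mean, sd) {
  if (sd == 0) return(max(mean, 0))
  a <- -mean / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# quantile of a normal truncated to [lo, hi]
.qtruncnorm_range <- function(u, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), length(u)))
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(p_lo + u * (p_hi - p_lo), mean, sd)
}

# Pearson correlation of the Gaussian copula that induces Spearman rho_s
.copula_rho <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Sample a synthetic cohort of eye geometries
#'
#' Draws `params$n_eyes` ground-truth eye geometries (all lengths in mm, in
#' the anatomic frame: origin at the corneal centre, +x nasal, +y superior).
#' Eyes violating anatomical containment (pupil inside cornea, hole inside
#' the pupil aperture) are resampled so the returned cohort contains no
#' invalid geometry. Fixed `seed` gives bit-identical output.
#'
#' @param params An [cohort_params()] object.
#' @param seed Integer seed.
#' @return A tibble with one row per eye: identifiers, laterality, ocular
#'   dimensions, signed hole and pupil centre coordinates, the fixed 360-um
#'   hole diameter, and kappa offsets.
#' @examples
#' eyes <- sample_cohort(cohort_params(n_eyes = 5), seed = 1)
#' eyes[, c("eye_id", "laterality", "cx_hole_mm", "cy_hole_mm")]
#' @export
sample_cohort <- function(params = cohort_params(), seed = 1L) {
  stopifnot(inherits(params, "icl_cohort_params"))
  withr::with_seed(as.integer(seed), {
    n <- as.integer(params$n_eyes)
    draw <- .draw_eyes(params, n)
    # resample eyes that violate containment until none remain
    bad <- which(!.eye_geometry_ok(draw))
    tries <- 0L
    while (length(bad) > 0 && tries < 100L) {
      redraw <- .draw_eyes(params, length(bad))
      draw[bad, ] <- redraw
      bad <- which(!.eye_geometry_ok(draw))
      tries <- tries + 1L
    }
    if (length(bad) > 0) {
      rlang::abort("could not sample anatomically valid eyes; check parameters",
        class = "icl_config_error")
    }
    draw$eye_id <- sprintf("eye_%04d", seq_len(n))
    # kappa coupled to the signed hole-minus-pupil components by rank
    hpx <- draw$cx_hole_mm - draw$cx_pupil_mm
    hpy <- draw$cy_hole_mm - draw$cy_pupil_mm
    draw$kappa_x_mm <- .rank_coupled_normal(hpx, params$kappa_rho_x,
      params$kappa_x_mean, params$kappa_x_sd)
    draw$kappa_y_mm <- .rank_coupled_normal(hpy, params$kappa_rho_y,
      params$kappa_y_mean, params$kappa_y_sd)
    dplyr::select(draw, "eye_id", dplyr::everything())
  })
}

.draw_eyes <- function(p, n) {
  # Gaussian copula per axis between hole and pupil magnitudes
  rgx <- .copula_rho(p$rho_x)
  rgy <- .copula_rho(p$rho_y)
  z1 <- stats::rnorm(n)
  z2 <- rgx * z1 + sqrt(1 - rgx^2) * stats::rnorm(n)
  z3 <- stats::rnorm(n)
  z4 <- rgy * z3 + sqrt(1 - rgy^2) * stats::rnorm(n)
  m_hx <- .qtruncnorm0(stats::pnorm(z1), p$hole_x_mean, p$hole_x_sd)
  m_px <- .qtruncnorm0(stats::pnorm(z2), p$pupil_x_mean, p$pupil_x_sd)
  m_hy <- .qtruncnorm0(stats::pnorm(z3), p$hole_y_mean, p$hole_y_sd)
  m_py <- .qtruncnorm0(stats::pnorm(z4), p$pupil_y_mean, p$pupil_y_sd)
  s_hx <- ifelse(stats::runif(n) < p$hole_p_nasal, 1, -1)
  s_hy <- ifelse(stats::runif(n) < p$hole_p_superior, 1, -1)
  s_px <- ifelse(stats::runif(n) < p$pupil_p_nasal, 1, -1)
  s_py <- ifelse(stats::runif(n) < p$pupil_p_superior, 1, -1)
  # pupil width and height are highly correlated within an eye (pupils are
  # nearly circular); draw them from a bivariate normal with r = 0.9
  zp1 <- stats::rnorm(n)
  zp2 <- 0.9 * zp1 + sqrt(1 - 0.9^2) * stats::rnorm(n)
  tibble::tibble(
    laterality = ifelse(stats::runif(n) < p$p_od, "OD", "OS"),
    # WTW restricted to the calibratable range of the method
    wtw_mm = .qtruncnorm_range(stats::runif(n), p$wtw_mean, p$wtw_sd, 9, 14),
    cornea_vertical_mm = pmax(stats::rnorm(n, p$cornea_v_mean, p$cornea_v_sd), 8.0),
    pupil_dh_mm = pmax(p$pupil_dh_mean + p$pupil_dh_sd * zp1, 1.5),
    pupil_dv_mm = pmax(p$pupil_dv_mean + p$pupil_dv_sd * zp2, 1.5),
    cx_hole_mm = s_hx * m_hx,
    cy_hole_mm = s_hy * m_hy,
    cx_pupil_mm = s_px * m_px,
    cy_pupil_mm = s_py * m_py,
    hole_diameter_um = 360
  )
}

# pupil inside cornea and hole (with its radius) inside the pupil aperture
.eye_geometry_ok <- function(g) {
  r_hole <- g$hole_diameter_um / 2000 # um -> mm radius
  pupil_in_cornea <-
    abs(g$cx_pupil_mm) + g$pupil_dh_mm / 2 < g$wtw_mm / 2 &
    abs(g$cy_pupil_mm) + g$pupil_dv_mm / 2 < g$cornea_vertical_mm / 2
  ah <- g$pupil_dh_mm / 2 - r_hole
  av <- g$pupil_dv_mm / 2 - r_hole
  hole_in_pupil <- ah > 0 & av > 0 &
    ((g$cx_hole_mm - g$cx_pupil_mm) / ah)^2 +
      ((g$cy_hole_mm - g$cy_pupil_mm) / av)^2 < 1
  hole_in_cornea <-
    abs(g$cx_hole_mm) + r_hole < g$wtw_mm / 2 &
    abs(g$cy_hole_mm) + r_hole < g$cornea_vertical_mm / 2
  pupil_in_cornea & hole_in_pupil & hole_in_cornea
}

# normal sample whose ranks are Gaussian-copula coupled to `anchor`
.rank_coupled_normal <- function(anchor, rho_s, mean, sd) {
  n <- length(anchor)
  rg <- .copula_rho(rho_s)
  # normal scores of the anchor's ranks
  z1 <- stats::qnorm(rank(anchor, ties.method = "first") / (n + 1))
  z2 <- rg * z1 + sqrt(1 - rg^2) * stats::rnorm(n)
  mean + sd * z2
}

#' Write / read a cohort ground-truth table
#'
#' Plain CSV round-trip of the per-eye geometry table with full numeric
#' precision.
#'
#' @param cohort Tibble as returned by [sample_cohort()].
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns the tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  message("wrote cohort table: ", path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
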