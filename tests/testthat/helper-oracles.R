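# Independent oracles and fixture builders shared across test files.

# a single ground-truth eye geometry row with controllable offsets (mm)
make_test_eye <- function(hole_x = 0.10, hole_y = 0.30,
                          pupil_x = 0.25, pupil_y = 0.05,
                          wtw = 10.28, cornea_v = 9.69,
                          pupil_dh = 2.54, pupil_dv = 2.43,
                          laterality = "OD", eye_id = "eye_test",
                          hole_um = 360) {
  tibble::tibble(
    eye_id = eye_id, laterality = laterality,
    wtw_mm = wtw, cornea_vertical_mm = cornea_v,
    pupil_dh_mm = pupil_dh, pupil_dv_mm = pupil_dv,
    cx_hole_mm = hole_x, cy_hole_mm = hole_y,
    cx_pupil_mm = pupil_x, cy_pupil_mm = pupil_y,
    hole_diameter_um = hole_um,
    kappa_x_mm = 0.1, kappa_y_mm = 0.0
  )
}

# Brute-force two-sided paired Wilcoxon p by enumerating all 2^n sign
# assignments of the observed absolute ranks (ties -> average ranks).
enum_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  vs <- vapply(0:(2^n - 1), function(m) {
    sel <- bitwAnd(m, 2^(0:(n - 1))) > 0
    sum(r[sel])
  }, numeric(1))
  lower <- mean(vs <= v_obs)
  upper <- mean(vs >= v_obs)
  min(1, 2 * min(lower, upper))
}

# Numeric longest-chord scan of an ellipse given geometric parameters:
# returns the intersection of the longest horizontal and vertical chords,
# located by root-finding on a finite-difference derivative of the chord
# length (no use of the algebraic centre formula).
chord_intersection <- function(cx, cy, a, b, rot) {
  # conic coefficients from the geometric construction
  co <- cos(rot)
  si <- sin(rot)
  A <- (co / a)^2 + (si / b)^2
  B <- 2 * co * si * (1 / a^2 - 1 / b^2)
  C <- (si / a)^2 + (co / b)^2
  D <- -2 * A * cx - B * cy
  E <- -2 * C * cy - B * cx
  F <- A * cx^2 + B * cx * cy + C * cy^2 - 1
  # squared horizontal chord length at height y: solve the conic for its two
  # x-roots and take their squared separation (quadratic in y, so the
  # maximiser is located exactly by a three-point parabola vertex)
  h_chord2 <- function(y) {
    disc <- (B * y + D)^2 - 4 * A * (C * y^2 + E * y + F)
    ifelse(disc > 0, disc / A^2, -Inf)
  }
  v_chord2 <- function(x) {
    disc <- (B * x + E)^2 - 4 * C * (A * x^2 + D * x + F)
    ifelse(disc > 0, disc / C^2, -Inf)
  }
  solve_max <- function(fn, lo, hi) {
    grid <- seq(lo, hi, length.out = 401)
    vals <- fn(grid)
    t0 <- grid[which.max(vals)]
    dh <- (hi - lo) / 400
    fm <- fn(t0 - dh)
    f0 <- fn(t0)
    fp <- fn(t0 + dh)
    t0 + dh * (fm - fp) / (2 * (fm - 2 * f0 + fp))
  }
  ey <- max(a, b)
  y_star <- solve_max(h_chord2, cy - 0.95 * ey, cy + 0.95 * ey)
  x_star <- solve_max(v_chord2, cx - 0.95 * ey, cx + 0.95 * ey)
  c(x = x_star, y = y_star)
}

# closed-form mean of N(mean, sd) truncated at zero (generator oracle)
truncnorm_mean <- function(mean, sd) {
  al <- -mean / sd
  mean + sd * dnorm(al) / (1 - pnorm(al))
}

truncnorm_sd <- function(mean, sd) {
  al <- -mean / sd
  lam <- dnorm(al) / (1 - pnorm(al))
  sqrt(sd^2 * (1 + al * lam - lam^2))
}
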