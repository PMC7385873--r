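#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to a set of 2-D points by the numerically stable
#' Halir-Flusser formulation of the direct conic fit with the ellipse
#' constraint \eqn{4AC - B^2 = 1}. The fit is invariant to point order and
#' equivariant under translation and uniform scaling of the input.
#'
#' The algebraic centre of the fitted conic coincides with the intersection
#' of the ellipse's longest horizontal and longest vertical chords, so it
#' realises the "intersection of the longest diameters" construction used to
#' define the corneal and pupil centres in en-face images.
#'
#' @param x,y Numeric vectors of pixel coordinates (at least 5 points), or a
#'   two-column matrix/data frame passed as `x`.
#' @param weights Optional non-negative point weights.
#' @return An object of class `icl_ellipse`: a list with `center` (x, y),
#'   `semi_axes` (a >= b), `rotation` in `[0, pi)` (angle of the major axis),
#'   `rms_residual` (RMS approximate point-to-ellipse distance) and
#'   `n_support` (number of points used).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 12)
#' fit <- fit_ellipse(50 + 20 * cos(th), 40 + 10 * sin(th))
#' fit$center
#' @export
fit_ellipse <- function(x, y = NULL, weights = NULL) {
  if (is.null(y)) {
    x <- as.matrix(x)
    y <- x[, 2]
    x <- x[, 1]
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 5) {
    rlang::abort("ellipse fit requires at least 5 points", class = "icl_fit_error")
  }
  w <- if (is.null(weights)) rep(1, n) else weights[keep]
  sw <- sqrt(pmax(w, 0))

  # condition: centre and scale the point cloud
  mx <- mean(x)
  my <- mean(y)
  sc <- mean(sqrt((x - mx)^2 + (y - my)^2))
  if (!is.finite(sc) || sc < .Machine$double.eps) {
    rlang::abort("degenerate point configuration", class = "icl_fit_error")
  }
  u <- (x - mx) / sc
  v <- (y - my) / sc

  D1 <- cbind(u^2, u * v, v^2) * sw
  D2 <- cbind(u, v, 1) * sw
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T2 <- tryCatch(-solve(S3, t(S2)), error = function(e) {
    rlang::abort("degenerate point configuration", class = "icl_fit_error")
  })
  M <- S1 + S2 %*% T2
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  # admissible solution satisfies the ellipse constraint 4ac - b^2 > 0
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  idx <- which(cond > 0)
  if (length(idx) == 0) {
    rlang::abort("no elliptical solution for these points", class = "icl_fit_error")
  }
  a1 <- vecs[, idx[1]]
  conic_c <- c(a1, as.vector(T2 %*% a1)) # A B C D E F in conditioned frame

  conic <- .conic_uncondition(conic_c, mx, my, sc)
  geom <- .conic_to_geom(conic)
  if (is.null(geom)) {
    rlang::abort("fitted conic is not an ellipse", class = "icl_fit_error")
  }

  res <- .conic_point_distance(conic, x, y)
  structure(
    list(
      center = geom$center,
      semi_axes = geom$semi_axes,
      rotation = geom$rotation,
      rms_residual = sqrt(mean(res^2)),
      n_support = n,
      conic = conic
    ),
    class = "icl_ellipse"
  )
}

#' @export
print.icl_ellipse <- function(x, ...) {
  cat(sprintf(
    "<ellipse> center (%.3f, %.3f) px, semi-axes (%.3f, %.3f) px, rotation %.1f deg, rms %.4f px, n = %d\n",
    x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
    x$rotation * 180 / pi, x$rms_residual, x$n_support
  ))
  invisible(x)
}

# map conic coefficients found on u = (x - mx)/s, v = (y - my)/s back to (x, y)
.conic_uncondition <- function(k, mx, my, s) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  A2 <- A / s^2
  B2 <- B / s^2
  C2 <- C / s^2
  D2 <- D / s - 2 * A * mx / s^2 - B * my / s^2
  E2 <- E / s - 2 * C * my / s^2 - B * mx / s^2
  F2 <- F + A * mx^2 / s^2 + B * mx * my / s^2 + C * my^2 / s^2 - D * mx / s - E * my / s
  out <- c(A2, B2, C2, D2, E2, F2)
  out / sqrt(sum(out[1:3]^2))
}

# geometric parameters of an ellipse-type conic Ax^2+Bxy+Cy^2+Dx+Ey+F=0
.conic_to_geom <- function(k) {
  if (k[1] + k[3] < 0) k <- -k # normalise sign so the quadratic part is PD
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  disc <- 4 * A * C - B^2
  if (disc <= 0) return(NULL)
  cx <- (B * E - 2 * C * D) / disc
  cy <- (B * D - 2 * A * E) / disc
  F0 <- F + (D * cx + E * cy) / 2
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  ei <- eigen(Q, symmetric = TRUE)
  lam <- ei$values
  if (any(-F0 / lam <= 0)) return(NULL)
  ax <- sqrt(-F0 / lam) # eigen() sorts decreasing, so ax[2] (smaller lambda) is the major axis
  major <- ei$vectors[, which.min(lam)]
  rot <- atan2(major[2], major[1]) %% pi
  a <- max(ax)
  b <- min(ax)
  if (abs(a - b) < 1e-12 * a) rot <- 0
  list(center = c(cx, cy), semi_axes = c(a, b), rotation = rot)
}

# first-order (Sampson) approximation of point-to-conic distance
.conic_point_distance <- function(k, x, y) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  q <- A * x^2 + B * x * y + C * y^2 + D * x + E * y + F
  gx <- 2 * A * x + B * y + D
  gy <- B * x + 2 * C * y + E
  abs(q) / pmax(sqrt(gx^2 + gy^2), .Machine$double.eps)
}

# points on an ellipse boundary (used by generators and tests)
.ellipse_points <- function(cx, cy, a, b, rot = 0, n = 64, theta = NULL) {
  th <- if (is.null(theta)) seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] else theta
  x0 <- a * cos(th)
  y0 <- b * sin(th)
  cbind(
    x = cx + x0 * cos(rot) - y0 * sin(rot),
    y = cy + x0 * sin(rot) + y0 * cos(rot)
  )
}

# implicit value: < 1 inside, 1 on boundary, > 1 outside
.ellipse_implicit <- function(x, y, cx, cy, a, b, rot = 0) {
  dx <- x - cx
  dy <- y - cy
  xr <- dx * cos(rot) + dy * sin(rot)
  yr <- -dx * sin(rot) + dy * cos(rot)
  (xr / a)^2 + (yr / b)^2
}
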