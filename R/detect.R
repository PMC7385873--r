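# EBImage stores images as [x, y]; this package uses im[row = y, col = x].
.to_ebi <- function(im) EBImage::Image(t(im))

# Otsu threshold of a numeric vector (rescaled into [0, 1] for EBImage)
.otsu_vec <- function(v) {
  rng <- range(v)
  if (diff(rng) < 1e-6) return(NA_real_)
  vs <- (v - rng[1]) / diff(rng)
  t0 <- EBImage::otsu(EBImage::Image(matrix(vs, ncol = 1)))
  rng[1] + as.numeric(t0) * diff(rng)
}

#' Remove a smooth illumination gradient
#'
#' Fits a quadratic polynomial surface to the image intensities (on a
#' subsampled grid) and divides it out, assuming multiplicative illumination.
#' The result is rescaled to preserve the original mean intensity.
#'
#' @param image Matrix image.
#' @param step Grid subsampling step for the surface fit.
#' @return Matrix of the same size.
#' @export
flatten_illumination <- function(image, step = 4L) {
  H <- nrow(image)
  W <- ncol(image)
  ii <- seq(1L, H, by = step)
  jj <- seq(1L, W, by = step)
  d <- expand.grid(y = ii, x = jj)
  d$z <- image[cbind(d$y, d$x)]
  d$xn <- (d$x - W / 2) / W
  d$yn <- (d$y - H / 2) / H
  fit <- stats::lm(z ~ xn + yn + I(xn^2) + I(xn * yn) + I(yn^2), data = d)
  xn <- matrix(rep((seq_len(W) - W / 2) / W, each = H), nrow = H)
  yn <- matrix(rep((seq_len(H) - H / 2) / H, times = W), nrow = H)
  b <- stats::coef(fit)
  surf <- b[1] + b[2] * xn + b[3] * yn + b[4] * xn^2 + b[5] * xn * yn + b[6] * yn^2
  surf <- pmax(surf, 1e-3)
  out <- image / surf
  out * mean(image) / mean(out)
}

# bilinear intensity sampling at real-valued pixel coordinates
.bilinear <- function(im, x, y) {
  H <- nrow(im)
  W <- ncol(im)
  x <- pmin(pmax(x, 1), W)
  y <- pmin(pmax(y, 1), H)
  x0 <- pmin(floor(x), W - 1L)
  y0 <- pmin(floor(y), H - 1L)
  fx <- x - x0
  fy <- y - y0
  im[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    im[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    im[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    im[cbind(y0 + 1, x0 + 1)] * fx * fy
}

# move integer contour points to the sub-pixel crossing of `level` along the
# ray from `center` through each point (profile sampled by interpolation)
.refine_boundary <- function(im, pts, center, level, reach = 2) {
  ts <- seq(-reach, reach, by = 0.25)
  dx <- pts[, 1] - center[1]
  dy <- pts[, 2] - center[2]
  nrm <- pmax(sqrt(dx^2 + dy^2), 1e-9)
  ux <- dx / nrm
  uy <- dy / nrm
  prof <- vapply(ts, function(t) {
    .bilinear(im, pts[, 1] + t * ux, pts[, 2] + t * uy) - level
  }, numeric(nrow(pts)))
  out <- pts
  for (i in seq_len(nrow(pts))) {
    p <- prof[i, ]
    cross <- which(p[-length(p)] * p[-1] <= 0 & p[-length(p)] != p[-1])
    if (length(cross) == 0) next
    k <- cross[which.min(abs(ts[cross]))]
    tk <- ts[k] - p[k] * (ts[k + 1] - ts[k]) / (p[k + 1] - p[k])
    out[i, 1] <- pts[i, 1] + tk * ux[i]
    out[i, 2] <- pts[i, 2] + tk * uy[i]
  }
  out
}

# connected components of a logical mask; returns label image and a table
.components <- function(mask) {
  lab <- EBImage::bwlabel(.to_ebi(mask * 1))
  areas <- tabulate(as.integer(EBImage::imageData(lab)))
  list(label = lab, areas = areas)
}

# 1-based (x, y) contour points of component `id` in a label image
.contour_points <- function(label, id) {
  oc <- EBImage::ocontour(label)[[id]]
  cbind(x = oc[, 1] + 1, y = oc[, 2] + 1)
}

#' Detect the pupil ellipse
#'
#' Locates the pupil as the largest dark connected region of plausible pupil
#' scale inside the limbus. The threshold is anchored on the intensity
#' distribution of the illumination-flattened iris region: halfway between
#' its dark tail (the pupil interior) and its median (the iris), which stays
#' reliable even when the pupil covers only a small fraction of the iris
#' disk. The component boundary is refined to sub-pixel positions and
#' fitted with the direct least-squares ellipse.
#'
#' @param image Matrix image in `[0, 1]`.
#' @param min_diameter_px,max_diameter_px Acceptable equivalent-diameter
#'   bounds for the pupil component.
#' @param limbus Optional `icl_ellipse` for the limbus; detected on the fly
#'   when missing.
#' @return An `icl_ellipse`.
#' @export
detect_pupil <- function(image, min_diameter_px = 20, max_diameter_px = 150,
                         limbus = NULL) {
  flat <- flatten_illumination(image)
  if (stats::sd(flat) < 0.01) {
    rlang::abort("no structure found: image is uniform", class = "icl_detect_error")
  }
  if (is.null(limbus)) limbus <- detect_limbus(image)
  H <- nrow(image)
  W <- ncol(image)
  xs <- matrix(rep(seq_len(W), each = H), nrow = H)
  ys <- matrix(rep(seq_len(H), times = W), nrow = H)
  region <- .ellipse_implicit(xs, ys, limbus$center[1], limbus$center[2],
    0.85 * limbus$semi_axes[1], 0.85 * limbus$semi_axes[2],
    limbus$rotation) < 1
  vals <- flat[region]
  dark_tail <- stats::quantile(vals, 0.002)
  iris_med <- stats::median(vals)
  if (iris_med - dark_tail < 0.1) {
    rlang::abort("no pupil-scale dark region inside the limbus",
      class = "icl_detect_error")
  }
  t2 <- (dark_tail + iris_med) / 2
  mask <- region & flat < t2
  cc <- .components(mask)
  dia <- 2 * sqrt(cc$areas / pi)
  ok <- which(dia >= min_diameter_px & dia <= max_diameter_px)
  if (length(ok) == 0) {
    rlang::abort(
      sprintf(
        "no pupil candidate with equivalent diameter in [%g, %g] px (found: %s)",
        min_diameter_px, max_diameter_px,
        if (length(dia)) paste(round(sort(dia, decreasing = TRUE)[1:3], 1),
          collapse = ", ") else "none"
      ),
      class = "icl_detect_error"
    )
  }
  id <- ok[which.max(cc$areas[ok])]
  filled <- EBImage::fillHull(cc$label == id)
  lab <- EBImage::bwlabel(filled)
  pts <- .contour_points(lab, 1)
  ctr <- colMeans(pts)
  pts <- .refine_boundary(flat, pts, ctr, t2)
  fit_ellipse(pts)
}

#' Detect the limbus ellipse
#'
#' Targets the iris/sclera boundary: the image is illumination-flattened,
#' thresholded with Otsu (dark side = iris + pupil), the largest component's
#' outer contour is refined to sub-pixel positions and a random-sample
#' consensus ellipse fit rejects outlying edge points before the final
#' direct fit on the inliers.
#'
#' @param image Matrix image in `[0, 1]`.
#' @param ransac_iter Number of consensus iterations.
#' @param inlier_tol_px Inlier distance tolerance, px.
#' @return An `icl_ellipse`.
#' @export
detect_limbus <- function(image, ransac_iter = 60L, inlier_tol_px = 1.5) {
  flat <- flatten_illumination(image)
  if (stats::sd(flat) < 0.01) {
    rlang::abort("no structure found: image is uniform", class = "icl_detect_error")
  }
  t1 <- .otsu_vec(as.vector(flat))
  mask <- flat < t1
  cc <- .components(mask)
  if (length(cc$areas) == 0) {
    rlang::abort("no dark region found for the limbus", class = "icl_detect_error")
  }
  id <- which.max(cc$areas)
  comp <- cc$label == id
  # a limbus truncated by the frame cannot be measured
  border <- sum(comp[1, ]) + sum(comp[nrow(comp), ]) +
    sum(comp[, 1]) + sum(comp[, ncol(comp)])
  if (border > 4) {
    rlang::abort("limbus touches the image border; eye not fully in frame",
      class = "icl_detect_error")
  }
  lab <- EBImage::bwlabel(EBImage::fillHull(comp))
  pts <- .contour_points(lab, 1)
  ctr <- colMeans(pts)
  pts <- .refine_boundary(flat, pts, ctr, t1)
  .ransac_ellipse(pts, iter = ransac_iter, tol = inlier_tol_px)
}

# consensus ellipse fit: minimal subsets, inlier count, refit on inliers
.ransac_ellipse <- function(pts, iter = 60L, tol = 1.5, sample_size = 8L) {
  n <- nrow(pts)
  if (n < sample_size) return(fit_ellipse(pts))
  withr::with_seed(20201L + n, {
    best <- NULL
    best_n <- -1L
    for (k in seq_len(iter)) {
      idx <- sample.int(n, sample_size)
      f <- tryCatch(fit_ellipse(pts[idx, , drop = FALSE]), error = function(e) NULL)
      if (is.null(f)) next
      d <- .conic_point_distance(f$conic, pts[, 1], pts[, 2])
      inl <- d < tol
      if (sum(inl) > best_n) {
        best_n <- sum(inl)
        best <- inl
      }
    }
    if (is.null(best) || best_n < 5) {
      fit_ellipse(pts)
    } else {
      fit_ellipse(pts[best, , drop = FALSE])
    }
  })
}

#' Detect the EVO-ICL central-hole ring
#'
#' Searches inside the pupil for the bright ring left by the 360-um central
#' hole with a matched annulus filter at the prior radius (circle mean minus
#' enclosed-disk mean, evaluated at every interior pixel), which embeds the
#' diameter prior directly and so resolves ties between candidate rings in
#' its favour. The best response is refined to sub-pixel accuracy as the
#' intensity-weighted centroid of the annulus (three passes); the measured
#' mean-radius diameter must agree with the prior within `tol_frac`.
#'
#' @param image Matrix image in `[0, 1]`.
#' @param pupil `icl_ellipse` for the pupil (search region).
#' @param expected_diameter_px Prior ring diameter in px (360 um / scale);
#'   7.5 px at the 48 um/px normalisation.
#' @param tol_frac Maximum relative deviation from the prior.
#' @return An `icl_ellipse` (circular: `a == b`).
#' @export
detect_hole <- function(image, pupil, expected_diameter_px = 7.5,
                        tol_frac = 0.2, min_response = 0.12) {
  H <- nrow(image)
  W <- ncol(image)
  xs <- matrix(rep(seq_len(W), each = H), nrow = H)
  ys <- matrix(rep(seq_len(H), times = W), nrow = H)
  inside <- .ellipse_implicit(xs, ys, pupil$center[1], pupil$center[2],
    pupil$semi_axes[1], pupil$semi_axes[2], pupil$rotation) < 1
  if (sum(inside) < 25) {
    rlang::abort("pupil region too small to search for the hole",
      class = "icl_detect_error")
  }
  base <- stats::median(image[inside])
  r0 <- expected_diameter_px / 2
  # matched annulus filter: mean intensity on the circle of the prior radius
  # minus the mean of the enclosed disk, evaluated on every interior pixel
  cand <- which(.ellipse_implicit(xs, ys, pupil$center[1], pupil$center[2],
    pupil$semi_axes[1], pupil$semi_axes[2], pupil$rotation) < 0.97 & inside,
    arr.ind = TRUE)
  cx_cand <- xs[cand]
  cy_cand <- ys[cand]
  ang <- seq(0, 2 * pi, length.out = 17)[-17]
  ring_samples <- vapply(ang, function(a) {
    .bilinear(image, cx_cand + r0 * cos(a), cy_cand + r0 * sin(a))
  }, numeric(length(cx_cand)))
  # lower-quartile along the circle: a true ring is bright on the whole
  # circumference, whereas a circle clipping the pupil boundary is not
  ring_mean <- apply(ring_samples, 1, function(v) sort(v)[5])
  disk_r <- max(r0 - 2, 0.5)
  disk_off <- rbind(c(0, 0), disk_r * cbind(cos(ang[c(1, 5, 9, 13)]),
    sin(ang[c(1, 5, 9, 13)])) / 2)
  disk_mean <- rowMeans(apply(disk_off, 1, function(o) {
    .bilinear(image, cx_cand + o[1], cy_cand + o[2])
  }))
  resp <- ring_mean - disk_mean
  if (max(resp) < min_response) {
    rlang::abort("no central-hole ring found inside the pupil",
      class = "icl_detect_error")
  }
  best <- which.max(resp)
  cx <- cx_cand[best]
  cy <- cy_cand[best]
  # sub-pixel refinement: intensity-weighted centroid over the annulus
  r <- r0
  for (pass in 1:3) {
    rad <- sqrt((xs - cx)^2 + (ys - cy)^2)
    ann <- inside & abs(rad - r0) <= 2.5
    w <- pmax(image[ann] - base, 0)
    if (sum(w) <= 0) break
    cx <- sum(xs[ann] * w) / sum(w)
    cy <- sum(ys[ann] * w) / sum(w)
    rr <- sqrt((xs[ann] - cx)^2 + (ys[ann] - cy)^2)
    r <- sum(rr * w) / sum(w)
  }
  if (abs(2 * r - expected_diameter_px) > tol_frac * expected_diameter_px) {
    rlang::abort(
      sprintf(
        "ring candidate diameter %.1f px outside %.0f%% of the %.1f px prior",
        2 * r, 100 * tol_frac, expected_diameter_px
      ),
      class = "icl_detect_error"
    )
  }
  rad <- sqrt((xs - cx)^2 + (ys - cy)^2)
  ann <- inside & abs(rad - r0) <= 2.5
  w <- pmax(image[ann] - base, 0)
  rr <- sqrt((xs[ann] - cx)^2 + (ys[ann] - cy)^2)
  rms <- sqrt(sum(w * (rr - r)^2) / sum(w))
  structure(
    list(
      center = c(cx, cy),
      semi_axes = c(r, r),
      rotation = 0,
      rms_residual = rms,
      n_support = sum(ann),
      conic = NULL
    ),
    class = "icl_ellipse"
  )
}

#' Segment limbus, pupil and central hole in one image
#'
#' Runs the three detectors in sequence and checks structural consistency
#' (pupil centre inside the limbus, hole centre inside the pupil).
#'
#' @param image Matrix image in `[0, 1]`.
#' @param expected_hole_px Ring-diameter prior in px; if `NULL` it is derived
#'   from `wtw_mm` and the fitted limbus (360 um at the implied scale).
#' @param wtw_mm Optional white-to-white used to derive the hole prior.
#' @param min_pupil_px,max_pupil_px Pupil size bounds passed to
#'   [detect_pupil()].
#' @return A list of class `icl_segmentation`: `limbus`, `pupil`, `hole`
#'   (`icl_ellipse` each) and logical quality `flags`.
#' @export
segment_eye <- function(image, expected_hole_px = NULL, wtw_mm = NULL,
                        min_pupil_px = 20, max_pupil_px = 150) {
  limbus <- detect_limbus(image)
  pupil <- detect_pupil(image, min_pupil_px, max_pupil_px, limbus = limbus)
  if (is.null(expected_hole_px)) {
    expected_hole_px <- if (is.null(wtw_mm)) {
      7.5
    } else {
      lim_h_px <- 2 * sqrt(limbus$semi_axes[1]^2 * cos(limbus$rotation)^2 +
        limbus$semi_axes[2]^2 * sin(limbus$rotation)^2)
      0.360 / (wtw_mm / lim_h_px)
    }
  }
  hole <- detect_hole(image, pupil, expected_diameter_px = expected_hole_px)
  flags <- c(
    pupil_in_limbus = .ellipse_implicit(
      pupil$center[1], pupil$center[2], limbus$center[1], limbus$center[2],
      limbus$semi_axes[1], limbus$semi_axes[2], limbus$rotation
    ) < 1,
    hole_in_pupil = .ellipse_implicit(
      hole$center[1], hole$center[2], pupil$center[1], pupil$center[2],
      pupil$semi_axes[1], pupil$semi_axes[2], pupil$rotation
    ) < 1
  )
  structure(list(limbus = limbus, pupil = pupil, hole = hole, flags = flags),
    class = "icl_segmentation")
}

#' @export
print.icl_segmentation <- function(x, ...) {
  cat("<segmentation>\n limbus: ")
  print(x$limbus)
  cat(" pupil:  ")
  print(x$pupil)
  cat(" hole:   ")
  print(x$hole)
  cat(" flags:", paste(names(x$flags), x$flags, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
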