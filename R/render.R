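#' Rendering configuration
#'
#' Controls how a ground-truth eye geometry is rasterised into a
#' slit-lamp-like grayscale image. The default scale of 48 um/px makes the
#' 360-um central hole 7.5 px across, the hole-fixed normalisation used when
#' annotating real photographs. Illumination is a multiplicative linear
#' gradient from a configurable azimuth, emulating diffuse temporal slit-lamp
#' lighting; additive Gaussian noise is applied last.
#'
#' @param scale_um_per_px Physical size of one pixel, micrometres.
#' @param width,height Image size in pixels; must contain the limbus.
#' @param illum_azimuth_deg Direction the light comes from, degrees
#'   (0 = +x raster, 90 = +y raster i.e. downwards; default 180 = from the
#'   left, the temporal side of a right-eye raster).
#' @param illum_strength Relative intensity swing across the frame (0 = flat).
#' @param noise_sd Additive Gaussian noise sd, fraction of dynamic range.
#' @param levels Named intensities in `[0, 1]` for `sclera`, `iris`, `pupil`
#'   and the hole `ring`.
#' @param ring_width_px Rendered thickness of the central-hole ring.
#' @param edge_width_px Width of the anti-aliased soft edge.
#' @param center_jitter_px Uniform sub-pixel jitter of the limbus centre
#'   placement (avoids grid-aligned fixtures).
#' @return A list of class `icl_render_config`.
#' @export
render_config <- function(scale_um_per_px = 48,
                          width = 320, height = 320,
                          illum_azimuth_deg = 180,
                          illum_strength = 0.15,
                          noise_sd = 0.02,
                          levels = c(sclera = 0.85, iris = 0.40,
                                     pupil = 0.08, ring = 0.60),
                          ring_width_px = 2,
                          edge_width_px = 1,
                          center_jitter_px = 0.5) {
  if (!is.finite(scale_um_per_px) || scale_um_per_px <= 0) {
    rlang::abort("invalid render config `scale_um_per_px`: must be > 0",
      class = "icl_config_error")
  }
  if (width < 16 || height < 16) {
    rlang::abort("invalid render config: image too small",
      class = "icl_config_error")
  }
  stopifnot(all(c("sclera", "iris", "pupil", "ring") %in% names(levels)))
  structure(as.list(environment()), class = "icl_render_config")
}

#' Render one eye geometry as a grayscale image
#'
#' Rasterises a ground-truth geometry (one row of [sample_cohort()], or any
#' list with the same fields) into a matrix image `im[row, col]` with values
#' in `[0, 1]`, origin at the top-left, x rightward (columns), y downward
#' (rows). The scene is drawn in the right-eye raster (+x raster = nasal) and
#' horizontally mirrored when `laterality` is `"OS"`, matching en-face
#' photographs of left eyes.
#'
#' @param geom One-row data frame or list with fields `wtw_mm`,
#'   `cornea_vertical_mm`, `pupil_dh_mm`, `pupil_dv_mm`, `cx_hole_mm`,
#'   `cy_hole_mm`, `cx_pupil_mm`, `cy_pupil_mm`, `hole_diameter_um`,
#'   `laterality` (and optionally `eye_id`).
#' @param cfg A [render_config()].
#' @param seed Integer seed for jitter and noise.
#' @return A list of class `icl_render`: `image` (matrix) and `truth`, a
#'   one-row tibble with every ground-truth centre in final-image pixel
#'   coordinates plus the scale.
#' @examples
#' eye <- sample_cohort(cohort_params(n_eyes = 1), seed = 2)
#' r <- render_eye(eye, render_config(noise_sd = 0), seed = 2)
#' dim(r$image)
#' @export
render_eye <- function(geom, cfg = render_config(), seed = 1L) {
  g <- as.list(as.data.frame(geom)[1, ])
  stopifnot(inherits(cfg, "icl_render_config"))
  scale_mm <- cfg$scale_um_per_px / 1000
  W <- cfg$width
  H <- cfg$height

  withr::with_seed(as.integer(seed), {
    j <- stats::runif(2, -cfg$center_jitter_px, cfg$center_jitter_px)
    # limbus centre in OD raster px
    lcx <- (W + 1) / 2 + j[1]
    lcy <- (H + 1) / 2 + j[2]
    la <- g$wtw_mm / 2 / scale_mm           # semi-axes px
    lb <- g$cornea_vertical_mm / 2 / scale_mm
    if (lcx - la < 1 || lcx + la > W || lcy - lb < 1 || lcy + lb > H) {
      rlang::abort("limbus ellipse exceeds the image frame",
        class = "icl_render_error")
    }
    # anatomic mm -> OD raster px (x: +nasal = +raster x; y: +superior = -raster y)
    pcx <- lcx + g$cx_pupil_mm / scale_mm
    pcy <- lcy - g$cy_pupil_mm / scale_mm
    hcx <- lcx + g$cx_hole_mm / scale_mm
    hcy <- lcy - g$cy_hole_mm / scale_mm
    pa <- g$pupil_dh_mm / 2 / scale_mm
    pb <- g$pupil_dv_mm / 2 / scale_mm
    r_hole <- g$hole_diameter_um / 1000 / 2 / scale_mm

    xs <- matrix(rep(seq_len(W), each = H), nrow = H)
    ys <- matrix(rep(seq_len(H), times = W), nrow = H)
    ew <- cfg$edge_width_px
    cov_edge <- function(d) pmin(1, pmax(0, 0.5 + d / ew))
    # signed distance to an axis-aligned ellipse along the radial ray
    ell_d <- function(cx, cy, a, b) {
      rr <- sqrt(((xs - cx) / a)^2 + ((ys - cy) / b)^2)
      rad <- sqrt((xs - cx)^2 + (ys - cy)^2)
      ifelse(rr > 0, rad * (1 / rr - 1), a)
    }
    lv <- cfg$levels
    im <- matrix(lv[["sclera"]], H, W)
    mix <- function(im, level, t) im * (1 - t) + level * t
    im <- mix(im, lv[["iris"]], cov_edge(ell_d(lcx, lcy, la, lb)))
    im <- mix(im, lv[["pupil"]], cov_edge(ell_d(pcx, pcy, pa, pb)))
    if (r_hole > 0) {
      rad <- sqrt((xs - hcx)^2 + (ys - hcy)^2)
      d_ring <- cfg$ring_width_px / 2 - abs(rad - r_hole)
      im <- mix(im, lv[["ring"]], cov_edge(d_ring))
    }
    if (cfg$illum_strength > 0) {
      az <- cfg$illum_azimuth_deg * pi / 180
      proj <- ((xs - (W + 1) / 2) * cos(az) + (ys - (H + 1) / 2) * sin(az)) /
        sqrt(W^2 + H^2)
      im <- im * (1 + cfg$illum_strength * proj)
    }
    if (cfg$noise_sd > 0) {
      im <- im + matrix(stats::rnorm(H * W, 0, cfg$noise_sd), H, W)
    }
    im <- pmin(pmax(im, 0), 1)

    truth <- tibble::tibble(
      eye_id = if (!is.null(g$eye_id)) g$eye_id else NA_character_,
      laterality = g$laterality,
      scale_um_per_px = cfg$scale_um_per_px,
      limbus_x_px = lcx, limbus_y_px = lcy,
      pupil_x_px = pcx, pupil_y_px = pcy,
      hole_x_px = hcx, hole_y_px = hcy,
      hole_diameter_px = 2 * r_hole
    )
    if (identical(g$laterality, "OS")) {
      im <- mirror_image(im, "OS")
      for (col in c("limbus_x_px", "pupil_x_px", "hole_x_px")) {
        truth[[col]] <- W + 1 - truth[[col]]
      }
    }
    structure(list(image = im, truth = truth), class = "icl_render")
  })
}

#' Mirror an image according to laterality
#'
#' Left-eye (OS) images are flipped about the vertical axis so that the
#' raster +x direction is nasal for both eyes; right-eye (OD) images pass
#' through unchanged. Applying the flip twice restores the original.
#'
#' @param image Matrix image.
#' @param laterality `"OD"` or `"OS"`.
#' @return The (possibly flipped) matrix.
#' @export
mirror_image <- function(image, laterality) {
  laterality <- match.arg(laterality, c("OD", "OS"))
  if (laterality == "OD") image else image[, ncol(image):1, drop = FALSE]
}

#' Write / read a grayscale image as PNG
#'
#' @param image Matrix with values in `[0, 1]`.
#' @param path File path.
#' @return `write_eye_image()` returns `path` invisibly; `read_eye_image()`
#'   returns the matrix.
#' @export
write_eye_image <- function(image, path) {
  png::writePNG(image, path)
  message("wrote image: ", path)
  invisible(path)
}

#' @rdname write_eye_image
#' @export
read_eye_image <- function(path) {
  im <- png::readPNG(path)
  if (length(dim(im)) == 3) im <- im[, , 1]
  im
}
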