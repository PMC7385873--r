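# longest horizontal chord of an ellipse (passes through its centre)
.ellipse_h_diameter <- function(e) {
  2 * sqrt(e$semi_axes[1]^2 * cos(e$rotation)^2 +
    e$semi_axes[2]^2 * sin(e$rotation)^2)
}

#' Pixel-to-millimetre calibration
#'
#' The absolute scale of an en-face photograph is set by the preoperatively
#' measured white-to-white (WTW): magnification = WTW (mm) / horizontal
#' limbus diameter (px). The detected hole diameter is recorded alongside as
#' the hole-fixed normalisation reference (7.5 px when one pixel is 48 um).
#'
#' @param limbus `icl_ellipse` of the limbus.
#' @param hole Optional `icl_ellipse` of the central hole; its diameter is
#'   stored as `hole_px`.
#' @param wtw_mm White-to-white in mm; must lie in `[9, 14]`.
#' @return A list of class `icl_calibration` with `mm_per_px`, `wtw_mm`,
#'   `cornea_h_px` and `hole_px`.
#' @examples
#' e <- fit_ellipse(.ellipse_points(160, 160, 107.1, 101, n = 40))
#' calibrate(e, wtw_mm = 10.28)$mm_per_px
#' @export
calibrate <- function(limbus, hole = NULL, wtw_mm) {
  if (!is.finite(wtw_mm) || wtw_mm < 9 || wtw_mm > 14) {
    rlang::abort(sprintf("wtw_mm = %g outside the plausible range [9, 14] mm", wtw_mm),
      class = "icl_input_error")
  }
  h_px <- .ellipse_h_diameter(limbus)
  if (!is.finite(h_px) || h_px <= 0) {
    rlang::abort("limbus horizontal diameter must be > 0", class = "icl_input_error")
  }
  structure(
    list(
      mm_per_px = wtw_mm / h_px,
      wtw_mm = wtw_mm,
      cornea_h_px = h_px,
      hole_px = if (is.null(hole)) NA_real_ else sum(hole$semi_axes)
    ),
    class = "icl_calibration"
  )
}

#' @export
print.icl_calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration> %.5f mm/px (WTW %.2f mm / limbus %.2f px), hole %.2f px\n",
    x$mm_per_px, x$wtw_mm, x$cornea_h_px, x$hole_px
  ))
  invisible(x)
}

#' Convert segmented centres to the anatomic coordinate frame
#'
#' Places the origin at the limbus (corneal) centre, negates raster y so +y
#' is superior, and for left eyes negates x so +x is nasal for both
#' lateralities, then converts to millimetres with the calibration.
#'
#' @param seg An `icl_segmentation`.
#' @param cal An `icl_calibration`.
#' @param laterality `"OD"` or `"OS"`.
#' @param eye_id Optional identifier carried into the output.
#' @return One-row tibble with signed `cx_hole_mm`, `cy_hole_mm`,
#'   `cx_pupil_mm`, `cy_pupil_mm` (+x nasal, +y superior).
#' @export
to_anatomic_frame <- function(seg, cal, laterality, eye_id = NA_character_) {
  laterality <- match.arg(laterality, c("OD", "OS"))
  if (!all(seg$flags)) {
    rlang::abort(
      paste("segmentation failed quality flags:",
        paste(names(seg$flags)[!seg$flags], collapse = ", ")),
      class = "icl_detect_error"
    )
  }
  m <- cal$mm_per_px
  sx <- if (laterality == "OS") -1 else 1
  conv <- function(e) {
    c(
      x = sx * (e$center[1] - seg$limbus$center[1]) * m,
      y = -(e$center[2] - seg$limbus$center[2]) * m
    )
  }
  h <- conv(seg$hole)
  p <- conv(seg$pupil)
  tibble::tibble(
    eye_id = eye_id,
    laterality = laterality,
    wtw_mm = cal$wtw_mm,
    cx_hole_mm = h[["x"]], cy_hole_mm = h[["y"]],
    cx_pupil_mm = p[["x"]], cy_pupil_mm = p[["y"]]
  )
}

#' Classify an offset vector into an anatomic quadrant
#'
#' `y >= 0` is superior, `x >= 0` nasal; a component exactly zero is
#' assigned to the superior/nasal side and flagged as a boundary case.
#'
#' @param x,y Signed components, +x nasal, +y superior (vectorised).
#' @return Tibble with `quadrant` (e.g. `"superior-nasal"`) and logical
#'   `boundary`.
#' @examples
#' classify_quadrant(c(0.1, -0.1, 0), c(0.2, -0.2, 0))
#' @export
classify_quadrant <- function(x, y) {
  tibble::tibble(
    quadrant = paste0(
      ifelse(y >= 0, "superior", "inferior"), "-",
      ifelse(x >= 0, "nasal", "temporal")
    ),
    boundary = x == 0 | y == 0
  )
}

#' Complete a centration record with distances and quadrants
#'
#' From signed hole and pupil coordinates (columns `cx_hole_mm`,
#' `cy_hole_mm`, `cx_pupil_mm`, `cy_pupil_mm`) computes the Euclidean
#' distances \eqn{D = \sqrt{X^2 + Y^2}} for hole-to-cornea, pupil-to-cornea
#' and hole-to-pupil, the unsigned component magnitudes, the signed
#' hole-minus-pupil components, and the quadrant classification of each
#' vector. Any further columns (e.g. kappa offsets) pass through.
#'
#' @param records Tibble with signed coordinate columns, one row per eye.
#' @return The input with columns `d_hc_mm`, `d_pc_mm`, `d_hp_mm`,
#'   `dhx_mm`, `dhy_mm`, `dpx_mm`, `dpy_mm`, `dhpx_mm`, `dhpy_mm`,
#'   `quad_hc`, `quad_pc`, `quad_hp` (+ `_boundary` flags) appended.
#' @examples
#' compute_distances(tibble::tibble(
#'   cx_hole_mm = 0.3, cy_hole_mm = 0.4, cx_pupil_mm = 0, cy_pupil_mm = 0
#' ))[, c("d_hc_mm", "d_pc_mm", "d_hp_mm")]
#' @export
compute_distances <- function(records) {
  need <- c("cx_hole_mm", "cy_hole_mm", "cx_pupil_mm", "cy_pupil_mm")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    rlang::abort(paste("missing coordinate columns:", paste(miss, collapse = ", ")),
      class = "icl_input_error")
  }
  out <- dplyr::mutate(
    records,
    d_hc_mm = sqrt(.data$cx_hole_mm^2 + .data$cy_hole_mm^2),
    d_pc_mm = sqrt(.data$cx_pupil_mm^2 + .data$cy_pupil_mm^2),
    dhpx_mm = .data$cx_hole_mm - .data$cx_pupil_mm,
    dhpy_mm = .data$cy_hole_mm - .data$cy_pupil_mm,
    d_hp_mm = sqrt(.data$dhpx_mm^2 + .data$dhpy_mm^2),
    dhx_mm = abs(.data$cx_hole_mm),
    dhy_mm = abs(.data$cy_hole_mm),
    dpx_mm = abs(.data$cx_pupil_mm),
    dpy_mm = abs(.data$cy_pupil_mm)
  )
  qhc <- classify_quadrant(out$cx_hole_mm, out$cy_hole_mm)
  qpc <- classify_quadrant(out$cx_pupil_mm, out$cy_pupil_mm)
  qhp <- classify_quadrant(out$dhpx_mm, out$dhpy_mm)
  dplyr::mutate(
    out,
    quad_hc = qhc$quadrant, quad_hc_boundary = qhc$boundary,
    quad_pc = qpc$quadrant, quad_pc_boundary = qpc$boundary,
    quad_hp = qhp$quadrant, quad_hp_boundary = qhp$boundary
  )
}

#' Measure one eye image end-to-end
#'
#' Segments the image, calibrates with the supplied white-to-white, converts
#' to the anatomic frame and completes the centration record.
#'
#' @param image Matrix image in `[0, 1]`.
#' @param wtw_mm White-to-white, mm.
#' @param laterality `"OD"` or `"OS"`.
#' @param eye_id Optional identifier.
#' @param ... Passed to [segment_eye()].
#' @return One-row centration-record tibble (see [compute_distances()]).
#' @export
measure_eye <- function(image, wtw_mm, laterality, eye_id = NA_character_, ...) {
  seg <- segment_eye(image, wtw_mm = wtw_mm, ...)
  cal <- calibrate(seg$limbus, seg$hole, wtw_mm)
  rec <- to_anatomic_frame(seg, cal, laterality, eye_id = eye_id)
  compute_distances(rec)
}

#' Measure a list of rendered or loaded images
#'
#' Maps [measure_eye()] over images, joining per-eye metadata (white-to-white,
#' laterality, optional kappa offsets) by `eye_id`. Eyes that fail detection
#' are dropped with a message and counted in the `failures` attribute.
#'
#' @param images Named list of matrix images (names = eye IDs), or a list of
#'   `icl_render` objects.
#' @param metadata Tibble with `eye_id`, `wtw_mm`, `laterality` and
#'   optionally `kappa_x_mm`, `kappa_y_mm`.
#' @param ... Passed to [measure_eye()].
#' @return Centration-record tibble, one row per successfully measured eye,
#'   with attribute `failures` (named character of error messages).
#' @export
measure_cohort <- function(images, metadata, ...) {
  if (length(images) > 0 && inherits(images[[1]], "icl_render")) {
    ids <- vapply(images, function(r) r$truth$eye_id, character(1))
    images <- lapply(images, function(r) r$image)
    names(images) <- ids
  }
  stopifnot(!is.null(names(images)), all(c("eye_id", "wtw_mm", "laterality") %in% names(metadata)))
  fails <- character(0)
  rows <- lapply(names(images), function(id) {
    md <- metadata[metadata$eye_id == id, ]
    if (nrow(md) != 1 || !is.finite(md$wtw_mm)) {
      fails[[id]] <<- "missing or invalid metadata field `wtw_mm`"
      message("skipping ", id, ": ", fails[[id]])
      return(NULL)
    }
    tryCatch(
      {
        rec <- measure_eye(images[[id]], md$wtw_mm, md$laterality, eye_id = id, ...)
        if (all(c("kappa_x_mm", "kappa_y_mm") %in% names(md))) {
          rec$kappa_x_mm <- md$kappa_x_mm
          rec$kappa_y_mm <- md$kappa_y_mm
        }
        rec
      },
      error = function(e) {
        fails[[id]] <<- conditionMessage(e)
        message("skipping ", id, ": ", conditionMessage(e))
        NULL
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- fails
  out
}
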