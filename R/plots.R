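#' Scatter plot of offset vectors around a reference centre
#'
#' Reproduces the standard centration scatter: one point per eye, crosshairs
#' through the reference centre at (0, 0), +x nasal and +y superior.
#'
#' @param records Centration-record tibble (see [compute_distances()]).
#' @param target `"hole"` or `"pupil"`: which centre to plot.
#' @param reference `"cornea"` or `"pupil"`: the centre placed at the origin.
#' @return A ggplot object.
#' @export
plot_centration <- function(records,
                            target = c("hole", "pupil"),
                            reference = c("cornea", "pupil")) {
  target <- match.arg(target)
  reference <- match.arg(reference)
  if (target == "pupil" && reference == "pupil") {
    rlang::abort("cannot plot the pupil against itself", class = "icl_input_error")
  }
  d <- if (target == "hole" && reference == "cornea") {
    dplyr::transmute(records, x = .data$cx_hole_mm, y = .data$cy_hole_mm)
  } else if (target == "pupil") {
    dplyr::transmute(records, x = .data$cx_pupil_mm, y = .data$cy_pupil_mm)
  } else {
    dplyr::transmute(records, x = .data$dhpx_mm, y = .data$dhpy_mm)
  }
  lab <- c(hole = "central hole", pupil = "pupil centre")[[target]]
  ref <- c(cornea = "corneal centre", pupil = "pupil centre")[[reference]]
  lim <- max(abs(c(d$x, d$y)), 0.1) * 1.1
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(-lim, lim), ylim = c(-lim, lim)) +
    ggplot2::labs(
      x = "x (mm, + nasal)", y = "y (mm, + superior)",
      title = sprintf("%s relative to the %s", lab, ref)
    ) +
    ggplot2::theme_minimal()
}

#' Quadrant percentage chart of a cohort summary
#'
#' @param object An `icl_cohort_summary`.
#' @param ... Unused.
#' @return A ggplot object with one panel per offset vector.
#' @importFrom ggplot2 autoplot
#' @method autoplot icl_cohort_summary
#' @export
autoplot.icl_cohort_summary <- function(object, ...) {
  d <- purrr::imap_dfr(object$quadrants, function(q, nm) {
    dplyr::mutate(q, vector = gsub("_", " ", nm))
  })
  d$quadrant <- factor(d$quadrant, levels = .quadrant_levels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$quadrant, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~vector) +
    ggplot2::labs(x = NULL, y = "eyes (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
ggplot2::autoplot

#' Overlay a segmentation on an image (debug view)
#'
#' @param image Matrix image.
#' @param seg An `icl_segmentation`.
#' @return A ggplot object showing the image with the three fitted ellipses.
#' @export
plot_segmentation <- function(image, seg) {
  H <- nrow(image)
  df <- tibble::tibble(
    x = rep(seq_len(ncol(image)), each = H),
    y = rep(seq_len(H), times = ncol(image)),
    v = as.vector(image)
  )
  ell_df <- purrr::imap_dfr(seg[c("limbus", "pupil", "hole")], function(e, nm) {
    p <- .ellipse_points(e$center[1], e$center[2], e$semi_axes[1],
      e$semi_axes[2], e$rotation, n = 120)
    tibble::tibble(x = p[, 1], y = p[, 2], structure = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$v)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_path(
      data = ell_df,
      ggplot2::aes(colour = .data$structure, group = .data$structure),
      linewidth = 0.4
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
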