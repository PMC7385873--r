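#' Percentage with half-away-from-zero rounding
#'
#' `100 * count / total` rounded to two decimals with ties going away from
#' zero (so 95.505 prints as 95.51, matching clinical-table convention
#' rather than IEEE round-half-even).
#'
#' @param count,total Non-negative counts, `count <= total`, `total > 0`.
#' @return Numeric percentage.
#' @examples
#' percent(85, 89)
#' @export
percent <- function(count, total) {
  if (any(total <= 0)) {
    rlang::abort("percent(): total must be > 0", class = "icl_input_error")
  }
  if (any(count < 0 | count > total)) {
    rlang::abort("percent(): count must lie in [0, total]", class = "icl_input_error")
  }
  floor(100 * count / total * 100 + 0.5) / 100
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test with the classic zero-handling convention: zero
#' differences are dropped before ranking. For 25 or fewer nonzero pairs the
#' exact null distribution of the positive-rank sum is computed by
#' convolution over the (possibly tied, average) ranks; above that a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. The statistic is V, the sum of ranks of positive differences.
#'
#' @param a,b Paired numeric samples of equal length (>= 5 pairs).
#' @param exact_max Largest number of nonzero pairs for which the exact
#'   distribution is enumerated.
#' @return List of class `icl_wilcoxon`: `statistic`, `p_value`, `n` (nonzero
#'   pairs), `exact`, `all_zero` (TRUE when every difference is zero, in
#'   which case `p_value = 1`).
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 5, 8, 9, 11), c(1, 1, 2, 4, 4, 5))
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25L) {
  if (length(a) != length(b)) {
    rlang::abort("paired samples must have equal length", class = "icl_input_error")
  }
  if (length(a) < 5) {
    rlang::abort("need at least 5 pairs", class = "icl_input_error")
  }
  d <- a - b
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(
      list(statistic = NA_real_, p_value = 1, n = 0L, exact = TRUE, all_zero = TRUE),
      class = "icl_wilcoxon"
    ))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: convolve the distribution of sum of included 2*ranks
    # (doubling makes tied average ranks integer)
    r2 <- as.integer(round(2 * r))
    S <- sum(r2)
    f <- numeric(S + 1)
    f[1] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1):(S + 1)] <- g[(ri + 1):(S + 1)] + f[1:(S + 1 - ri)]
      f <- g
    }
    f <- f / 2^n
    V2 <- as.integer(round(2 * V))
    lower <- sum(f[seq_len(V2 + 1)])
    upper <- sum(f[(V2 + 1):(S + 1)])
    p <- min(1, 2 * min(lower, upper))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(V - mu) * 0.5
    z <- (V - mu - cc) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(
    list(statistic = V, p_value = p, n = n, exact = exact, all_zero = FALSE),
    class = "icl_wilcoxon"
  )
}

#' @export
print.icl_wilcoxon <- function(x, ...) {
  cat(sprintf(
    "<Wilcoxon signed-rank> V = %s, %s (n = %d nonzero pairs, %s)%s\n",
    format(x$statistic), format_p(x$p_value), x$n,
    if (x$exact) "exact" else "normal approx.",
    if (x$all_zero) " [all differences zero]" else ""
  ))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, with a two-sided p-value from the
#' t approximation on `n - 2` degrees of freedom.
#'
#' @param a,b Numeric samples of equal length (>= 5).
#' @return List of class `icl_spearman`: `estimate`, `p_value`, `n`,
#'   `degenerate` (TRUE when either sample has zero rank variance, in which
#'   case the estimate is `NA`).
#' @examples
#' spearman_rank(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
#' @export
spearman_rank <- function(a, b) {
  if (length(a) != length(b)) {
    rlang::abort("samples must have equal length", class = "icl_input_error")
  }
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]
  b <- b[keep]
  n <- length(a)
  if (n < 5) {
    rlang::abort("need at least 5 complete pairs", class = "icl_input_error")
  }
  ra <- rank(a)
  rb <- rank(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    return(structure(
      list(estimate = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE),
      class = "icl_spearman"
    ))
  }
  r <- stats::cor(ra, rb)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  structure(
    list(estimate = r, p_value = p, n = n, degenerate = FALSE),
    class = "icl_spearman"
  )
}

#' @export
print.icl_spearman <- function(x, ...) {
  cat(sprintf(
    "<Spearman> r = %.3f, %s (n = %d)%s\n",
    x$estimate, format_p(x$p_value), x$n,
    if (x$degenerate) " [degenerate ranks]" else ""
  ))
  invisible(x)
}

#' Format a p-value in clinical-report style
#'
#' @param p Numeric p-value.
#' @return `"p < 0.001"` below that threshold, else `"p = x.xxx"`.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "p = NA",
    ifelse(p < 0.001, "p < 0.001", sprintf("p = %.3f", p))
  )
}

.quadrant_levels <- c(
  "superior-nasal", "superior-temporal", "inferior-nasal", "inferior-temporal"
)

.quadrant_table <- function(quadrant) {
  n_total <- length(quadrant)
  counts <- table(factor(quadrant, levels = .quadrant_levels))
  tibble::tibble(
    quadrant = names(counts),
    count = as.integer(counts),
    percent = percent(as.integer(counts), n_total)
  )
}

#' Correlations of kappa offsets with lens-position components
#'
#' Spearman correlations of the kappa (pupil-offset) x/y components with the
#' unsigned hole-to-corneal-centre magnitudes and with the signed
#' hole-minus-pupil components.
#'
#' @param records Centration-record tibble (see [compute_distances()]);
#'   kappa columns `kappa_x_mm`, `kappa_y_mm` expected.
#' @return Tibble with one row per pair (`pair`, `r`, `p_value`, `n`,
#'   `available`); when kappa columns are missing every row is flagged
#'   unavailable.
#' @export
kappa_correlations <- function(records) {
  pairs <- list(
    "K-x ~ DHx" = c("kappa_x_mm", "dhx_mm"),
    "K-y ~ DHy" = c("kappa_y_mm", "dhy_mm"),
    "K-x ~ DHPx" = c("kappa_x_mm", "dhpx_mm"),
    "K-y ~ DHPy" = c("kappa_y_mm", "dhpy_mm")
  )
  purrr::map_dfr(names(pairs), function(nm) {
    cols <- pairs[[nm]]
    if (!all(cols %in% names(records)) ||
      all(is.na(records[[cols[1]]])) || all(is.na(records[[cols[2]]]))) {
      return(tibble::tibble(
        pair = nm, r = NA_real_, p_value = NA_real_,
        n = 0L, available = FALSE
      ))
    }
    s <- spearman_rank(records[[cols[1]]], records[[cols[2]]])
    tibble::tibble(
      pair = nm, r = s$estimate, p_value = s$p_value,
      n = s$n, available = !s$degenerate
    )
  })
}

#' Summarise a cohort of centration records
#'
#' Computes the published-table quantities: mean, sample SD (n - 1), min and
#' max of every distance metric; quadrant count/percentage tables for the
#' three offset vectors; paired Wilcoxon signed-rank comparisons of
#' hole-vs-pupil distances and components; Spearman correlations between the
#' paired metrics; and kappa-offset correlations when kappa metadata are
#' present. Tests require at least 5 eyes and are flagged unavailable below
#' that.
#'
#' @param records Centration-record tibble from [compute_distances()] /
#'   [measure_cohort()]; at least 2 rows.
#' @return Object of class `icl_cohort_summary` with elements `n`, `metrics`,
#'   `quadrants` (list of three tibbles), `wilcoxon`, `spearman`, `kappa`.
#' @export
summarize_cohort <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    rlang::abort("no records to summarise", class = "icl_input_error")
  }
  if (nrow(records) < 2) {
    rlang::abort("need at least 2 records for dispersion statistics",
      class = "icl_input_error")
  }
  metric_cols <- c(
    "d_hc_mm", "d_pc_mm", "d_hp_mm",
    "dhx_mm", "dhy_mm", "dpx_mm", "dpy_mm"
  )
  metrics <- purrr::map_dfr(metric_cols, function(mc) {
    v <- records[[mc]]
    tibble::tibble(
      metric = mc, mean = mean(v), sd = stats::sd(v),
      min = min(v), max = max(v)
    )
  })
  quadrants <- list(
    hole_vs_cornea = .quadrant_table(records$quad_hc),
    hole_vs_pupil = .quadrant_table(records$quad_hp),
    pupil_vs_cornea = .quadrant_table(records$quad_pc)
  )
  n <- nrow(records)
  tests_ok <- n >= 5
  comparisons <- list(
    "D(H-C) vs D(P-C)" = c("d_hc_mm", "d_pc_mm"),
    "DHx vs DPx" = c("dhx_mm", "dpx_mm"),
    "DHy vs DPy" = c("dhy_mm", "dpy_mm")
  )
  wilcoxon <- purrr::map_dfr(names(comparisons), function(nm) {
    cols <- comparisons[[nm]]
    if (!tests_ok) {
      return(tibble::tibble(
        comparison = nm, statistic = NA_real_, p_value = NA_real_,
        available = FALSE
      ))
    }
    w <- wilcoxon_signed_rank(records[[cols[1]]], records[[cols[2]]])
    tibble::tibble(
      comparison = nm, statistic = w$statistic, p_value = w$p_value,
      available = TRUE
    )
  })
  spearman <- purrr::map_dfr(names(comparisons), function(nm) {
    cols <- comparisons[[nm]]
    if (!tests_ok) {
      return(tibble::tibble(
        pair = nm, r = NA_real_, p_value = NA_real_, available = FALSE
      ))
    }
    s <- spearman_rank(records[[cols[1]]], records[[cols[2]]])
    tibble::tibble(
      pair = nm, r = s$estimate, p_value = s$p_value,
      available = !s$degenerate
    )
  })
  kappa <- if (tests_ok) kappa_correlations(records) else NULL
  structure(
    list(
      n = n, metrics = metrics, quadrants = quadrants,
      wilcoxon = wilcoxon, spearman = spearman, kappa = kappa
    ),
    class = "icl_cohort_summary"
  )
}

#' @export
print.icl_cohort_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Centration summary of %d eyes\n\n", x$n))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf(
      "  %-8s %.2f +/- %.2f mm (range %.2f ~ %.2f)\n",
      m$metric[i], m$mean[i], m$sd[i], m$min[i], m$max[i]
    ))
  }
  for (nm in names(x$quadrants)) {
    q <- x$quadrants[[nm]]
    cat("\n  ", gsub("_", " ", nm), ":\n", sep = "")
    for (i in seq_len(nrow(q))) {
      cat(sprintf("    %-18s %3d (%.2f%%)\n", q$quadrant[i], q$count[i], q$percent[i]))
    }
  }
  cat("\n  Wilcoxon signed-rank:\n")
  for (i in seq_len(nrow(x$wilcoxon))) {
    cat(sprintf(
      "    %-18s V = %s, %s\n", x$wilcoxon$comparison[i],
      format(x$wilcoxon$statistic[i]), format_p(x$wilcoxon$p_value[i])
    ))
  }
  cat("  Spearman:\n")
  for (i in seq_len(nrow(x$spearman))) {
    cat(sprintf(
      "    %-18s r = %.3f, %s\n", x$spearman$pair[i],
      x$spearman$r[i], format_p(x$spearman$p_value[i])
    ))
  }
  if (!is.null(x$kappa) && any(x$kappa$available)) {
    cat("  Kappa correlations:\n")
    for (i in seq_len(nrow(x$kappa))) {
      cat(sprintf(
        "    %-18s r = %.3f, %s\n", x$kappa$pair[i],
        x$kappa$r[i], format_p(x$kappa$p_value[i])
      ))
    }
  }
  invisible(x)
}

#' Tidy a cohort summary
#'
#' @param x An `icl_cohort_summary`.
#' @param ... Unused.
#' @return The per-metric summary tibble (metric, mean, sd, min, max).
#' @importFrom generics tidy
#' @method tidy icl_cohort_summary
#' @export
tidy.icl_cohort_summary <- function(x, ...) {
  x$metrics
}

#' One-row overview of a cohort summary
#'
#' @param x An `icl_cohort_summary`.
#' @param ... Unused.
#' @return One-row tibble with n, key means and the headline test results.
#' @importFrom generics glance
#' @method glance icl_cohort_summary
#' @export
glance.icl_cohort_summary <- function(x, ...) {
  g <- function(df, key, col, val) {
    v <- df[[val]][df[[key]] == col]
    if (length(v) == 1) v else NA_real_
  }
  tibble::tibble(
    n = x$n,
    mean_d_hc = g(x$metrics, "metric", "d_hc_mm", "mean"),
    mean_d_pc = g(x$metrics, "metric", "d_pc_mm", "mean"),
    mean_d_hp = g(x$metrics, "metric", "d_hp_mm", "mean"),
    p_dhc_dpc = g(x$wilcoxon, "comparison", "D(H-C) vs D(P-C)", "p_value"),
    p_dhx_dpx = g(x$wilcoxon, "comparison", "DHx vs DPx", "p_value"),
    p_dhy_dpy = g(x$wilcoxon, "comparison", "DHy vs DPy", "p_value"),
    r_dhx_dpx = g(x$spearman, "pair", "DHx vs DPx", "r"),
    r_dhy_dpy = g(x$spearman, "pair", "DHy vs DPy", "r")
  )
}

#' @export
generics::tidy

#' @export
generics::glance
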