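#' Relative nuclear abundance from compartment medians
#'
#' The per-time-point localisation measure is the ratio of the median nuclear
#' intensity to the median cytoplasmic intensity, optionally after
#' subtracting the bounding-box background median from both (used under
#' benign conditions where signal is close to background). A time point whose
#' corrected cytoplasm is non-positive yields `NA` and is counted in a
#' warning rather than failing the cell.
#'
#' @param nuc_median,cyt_median Compartment median intensities (a.u.).
#' @param bg_median Bounding-box background medians (required when
#'   `correct_bg = TRUE`).
#' @param correct_bg Subtract the background from both compartments first.
#' @return Numeric ratio vector (unitless), `NA` where undefined.
#' @examples
#' relative_nuclear_abundance(110, 100)                       # 1.1
#' relative_nuclear_abundance(110, 100, 10, correct_bg = TRUE) # 100/90
#' @export
relative_nuclear_abundance <- function(nuc_median, cyt_median,
                                       bg_median = NULL, correct_bg = FALSE) {
  if (correct_bg) {
    if (is.null(bg_median)) abort("bg_median required when correct_bg = TRUE")
    nuc <- nuc_median - bg_median
    cyt <- cyt_median - bg_median
  } else {
    nuc <- nuc_median
    cyt <- cyt_median
  }
  bad <- !is.finite(cyt) | cyt <= 0
  if (any(bad)) {
    warn(sprintf("%d time point(s) with non-positive cytoplasm dropped as NA",
                 sum(bad)))
    cyt[bad] <- NA_real_
  }
  nuc / cyt
}

#' Total nuclear occupancy of a ratio time series
#'
#' Summarises a cell's nuclear-localisation dynamics in one number: the
#' baseline is the mean of the `k_baseline` lowest relative abundances
#' (absorbing between-image intensity variation), and the occupancy is the
#' sum of (abundance - baseline) over all other time points divided by the
#' number of such points — an average excess, robust to series of unequal
#' length from imperfect tracking. Missing time points are removed before
#' ranking. The result is not clamped: with `k_baseline > 1`, noise can place
#' individual points below the baseline mean.
#'
#' @param ratio_series Relative nuclear abundances (one cell, chronological).
#' @param k_baseline Number of lowest points defining the baseline
#'   (default 4).
#' @return One-row tibble: `baseline`, `occupancy`, `n_other` (non-baseline
#'   points), `n_used` (observed points), `k_baseline`.
#' @examples
#' total_nuclear_occupancy(c(1, 1, 1, 1, 1.5, 2))  # occupancy 0.75
#' @export
total_nuclear_occupancy <- function(ratio_series, k_baseline = 4) {
  x <- ratio_series[!is.na(ratio_series)]
  n <- length(x)
  if (n <= k_baseline) {
    abort(sprintf("need more than k_baseline = %d observed points (got %d)",
                  k_baseline, n))
  }
  ord <- order(x)  # stable: duplicates taken in time order
  base_idx <- ord[seq_len(k_baseline)]
  baseline <- mean(x[base_idx])
  others <- x[-base_idx]
  tibble(baseline = baseline,
         occupancy = sum(others - baseline) / length(others),
         n_other = length(others), n_used = n,
         k_baseline = as.integer(k_baseline))
}

#' Occupancy robustness to the baseline size
#'
#' Recomputes the total nuclear occupancy for each baseline size in `k_set`
#' and reports the spread, verifying that conclusions do not hinge on the
#' choice of four baseline points.
#'
#' @inheritParams total_nuclear_occupancy
#' @param k_set Baseline sizes to try.
#' @return Tibble with one row per `k` (columns as
#'   [total_nuclear_occupancy()]), plus attribute `max_spread`, the largest
#'   pairwise occupancy difference.
#' @export
occupancy_robustness <- function(ratio_series, k_set = c(1, 2, 3, 4, 5)) {
  out <- dplyr::bind_rows(lapply(k_set, function(k) {
    total_nuclear_occupancy(ratio_series, k_baseline = k)
  }))
  attr(out, "max_spread") <- max(out$occupancy) - min(out$occupancy)
  out
}

#' Per-cell occupancy table from a long time-series table
#'
#' Computes the relative nuclear abundance per record, then the total nuclear
#' occupancy per cell. Cells with too few observed points are returned with
#' `NA` occupancy rather than dropped.
#'
#' @param cells Long tibble with columns `cell_id`, `nuc_median`,
#'   `cyt_median` and (if correcting) `bbox_bg_median`; rows in time order
#'   within cell.
#' @param correct_bg Background-correct the ratio (see
#'   [relative_nuclear_abundance()]).
#' @param k_baseline Baseline size.
#' @return Tibble: one row per cell with `baseline`, `occupancy`, `n_other`,
#'   `n_used`.
#' @export
compute_occupancy <- function(cells, correct_bg = FALSE, k_baseline = 4) {
  ratio <- suppressWarnings(relative_nuclear_abundance(
    cells$nuc_median, cells$cyt_median, cells$bbox_bg_median,
    correct_bg = correct_bg))
  groups <- split(ratio, factor(cells$cell_id, levels = unique(cells$cell_id)))
  rows <- purrr::imap(groups, function(r, id) {
    res <- tryCatch(total_nuclear_occupancy(r, k_baseline),
                    error = function(e) tibble(
                      baseline = NA_real_, occupancy = NA_real_,
                      n_other = NA_integer_, n_used = sum(!is.na(r)),
                      k_baseline = as.integer(k_baseline)))
    dplyr::bind_cols(tibble(cell_id = id), res)
  })
  dplyr::bind_rows(rows)
}

#' Linear regression of growth on Msn2 occupancy
#'
#' Ordinary least squares of microcolony growth rate (response) on total
#' nuclear occupancy (predictor), with a normal-theory 95% CI on the slope
#' and a pointwise confidence band for plotting. A negative slope means
#' cells in which Msn2 spends more time nuclear found slower-growing
#' colonies.
#'
#' @param data Per-cell data frame.
#' @param occupancy,rate Bare column names.
#' @param n_grid Prediction grid size.
#' @return Object of class `occupancy_fit` with `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
occupancy_growth_regression <- function(data, occupancy = occupancy,
                                        rate = rate, n_grid = 100) {
  df <- tibble(
    occupancy = eval_tidy(enquo(occupancy), data),
    rate = eval_tidy(enquo(rate), data)
  )
  df <- df[complete.cases(df), ]
  if (nrow(df) < 20) abort("need n >= 20 cells")
  if (var(df$occupancy) == 0) abort("zero occupancy variance")
  fit <- lm(rate ~ occupancy, data = df)
  sm <- summary(fit)
  slope <- coef(fit)[["occupancy"]]
  se <- sm$coefficients["occupancy", "Std. Error"]
  grid <- tibble(occupancy = seq(min(df$occupancy), max(df$occupancy),
                                 length.out = n_grid))
  pr <- predict(fit, newdata = grid, interval = "confidence", level = 0.95)
  curve <- tibble(occupancy = grid$occupancy, fit = pr[, "fit"],
                  conf_lo = pr[, "lwr"], conf_hi = pr[, "upr"])
  structure(list(fit = fit, slope = slope, slope_se = se,
                 conf_lo = slope - qnorm(0.975) * se,
                 conf_hi = slope + qnorm(0.975) * se,
                 p_value = sm$coefficients["occupancy", "Pr(>|t|)"],
                 curve = curve, data = df, n = nrow(df)),
            class = "occupancy_fit")
}

#' @export
tidy.occupancy_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "occupancy"),
         estimate = coef(x$fit),
         std_error = summary(x$fit)$coefficients[, "Std. Error"],
         p_value = summary(x$fit)$coefficients[, "Pr(>|t|)"])
}

#' @export
glance.occupancy_fit <- function(x, ...) {
  tibble(n = x$n, slope = x$slope, conf_lo = x$conf_lo, conf_hi = x$conf_hi,
         p_value = x$p_value, r_squared = summary(x$fit)$r.squared)
}

#' @export
autoplot.occupancy_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$occupancy, y = .data$rate)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_ribbon(data = object$curve,
                         ggplot2::aes(x = .data$occupancy, y = .data$fit,
                                      ymin = .data$conf_lo,
                                      ymax = .data$conf_hi),
                         alpha = 0.3, fill = "goldenrod") +
    ggplot2::geom_line(data = object$curve,
                       ggplot2::aes(y = .data$fit)) +
    ggplot2::labs(x = "total nuclear occupancy", y = "growth rate (1/h)")
}

#' Rank test between two groups of relative abundances
#'
#' Two-sided Wilcoxon-Mann-Whitney test, e.g. comparing Msn2 relative nuclear
#' abundance between a drug treatment and its vehicle control.
#'
#' @param group_a,group_b Numeric vectors (n >= 10 each).
#' @return One-row tibble: `statistic` (W), `p_value`, medians of each group.
#' @export
compare_relative_abundance <- function(group_a, group_b) {
  if (length(group_a) < 10 || length(group_b) < 10) {
    abort("need n >= 10 per group")
  }
  if (length(unique(c(group_a, group_b))) == 1) {
    abort("degenerate data: all values tied")
  }
  wt <- suppressWarnings(wilcox.test(group_a, group_b,
                                     alternative = "two.sided"))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         median_a = median(group_a), median_b = median(group_b))
}

#' @rdname compare_relative_abundance
#' @export
rank_compare <- compare_relative_abundance
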