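#' Two-stage fluorescence background correction
#'
#' Per colony, the local background (median intensity in the smallest
#' bounding rectangle outside the cell body) is subtracted from the raw cell
#' median; the minimum of these differences over the whole experiment (not
#' per plate) is then subtracted, anchoring the dimmest colony at zero and
#' making corrected values non-negative by construction.
#'
#' @param data Per-colony data frame.
#' @param raw,local_bg Bare column names of the raw cell median and local
#'   background median (a.u.).
#' @param out Name of the corrected column to add.
#' @return `data` with the corrected column appended and attribute
#'   `experiment_min` (the subtracted experiment-wide minimum).
#' @export
correct_intensities <- function(data, raw, local_bg,
                                out = "corrected_intensity") {
  r <- eval_tidy(enquo(raw), data)
  b <- eval_tidy(enquo(local_bg), data)
  if (length(r) != length(b)) abort("raw and local_bg differ in length")
  diffs <- r - b
  exp_min <- min(diffs)
  data[[out]] <- diffs - exp_min
  attr(data, "experiment_min") <- exp_min
  data
}

#' Spline smoother of reporter intensity on growth rate
#'
#' Penalized cubic regression spline (generalized additive model, smoothing
#' parameter by generalized cross-validation) of intensity on growth rate,
#' with a pointwise 95% confidence band. Captures the shape of the
#' expression-growth relationship without assuming linearity.
#'
#' @param data Per-colony data frame.
#' @param rate,intensity Bare column names.
#' @param k Spline basis dimension (default 10).
#' @param n_grid Evaluation grid size across the observed rate range.
#' @return Object of class `intensity_gam`: the \pkg{mgcv} fit plus a
#'   `curve` tibble (`rate`, `fit`, `conf_lo`, `conf_hi`). `tidy()` returns
#'   the curve; `autoplot()` draws it.
#' @export
intensity_growth_smoother <- function(data, rate = rate,
                                      intensity = reporter_intensity,
                                      k = 10, n_grid = 200) {
  df <- tibble(
    rate = eval_tidy(enquo(rate), data),
    intensity = eval_tidy(enquo(intensity), data)
  )
  df <- df[complete.cases(df), ]
  if (nrow(df) < 50) abort("need n >= 50 colonies")
  if (length(unique(df$rate)) <= k) {
    abort("too few unique growth rates for the spline basis")
  }
  fit <- mgcv::gam(intensity ~ s(rate, bs = "cr", k = k), data = df,
                   method = "GCV.Cp")
  grid <- tibble(rate = seq(min(df$rate), max(df$rate), length.out = n_grid))
  pr <- predict(fit, newdata = grid, se.fit = TRUE)
  curve <- tibble(rate = grid$rate, fit = as.numeric(pr$fit),
                  conf_lo = as.numeric(pr$fit - 1.96 * pr$se.fit),
                  conf_hi = as.numeric(pr$fit + 1.96 * pr$se.fit))
  structure(list(fit = fit, curve = curve, n = nrow(df)),
            class = "intensity_gam")
}

#' @export
tidy.intensity_gam <- function(x, ...) x$curve

#' @export
glance.intensity_gam <- function(x, ...) {
  s <- summary(x$fit)
  tibble(n = x$n, edf = sum(s$edf), r_sq = s$r.sq,
         gcv = x$fit$gcv.ubre[[1]])
}

#' @export
autoplot.intensity_gam <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$rate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_lo,
                                      ymax = .data$conf_hi), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::labs(x = "growth rate (1/h)", y = "corrected intensity (a.u.)")
}

#' Partitioning-around-medoids clustering of the rate-intensity plane
#'
#' Classic build+swap PAM (via \pkg{cluster}) on standardized (z-scored)
#' axes with Euclidean distance, used to separate the slower-growing
#' high-reporter sub-population from the fast-growing low-reporter majority.
#' Medoids are reported in original units.
#'
#' @param data Per-colony data frame.
#' @param x,y Bare column names of the two axes (growth rate and intensity).
#' @param k Number of clusters (default 2).
#' @param standardize Z-score the axes before clustering (default TRUE).
#' @return Object of class `pam_clusters`: `assignments` tibble (`x`, `y`,
#'   `cluster`), `medoids` tibble in original units, `fractions`, `k`.
#' @export
pam_cluster <- function(data, x = rate, y = reporter_intensity, k = 2,
                        standardize = TRUE) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n <= k) abort("need more points than clusters")
  mat <- cbind(xv, yv)
  zmat <- if (standardize) scale(mat) else mat
  fit <- cluster::pam(zmat, k = k, metric = "euclidean", do.swap = TRUE)
  assignments <- tibble(x = xv, y = yv, cluster = as.integer(fit$clustering))
  medoids <- tibble(cluster = seq_len(k),
                    x = xv[fit$id.med], y = yv[fit$id.med])
  fractions <- as.numeric(table(factor(fit$clustering, levels = seq_len(k))) / n)
  structure(list(assignments = assignments, medoids = medoids,
                 fractions = fractions, k = k, id_med = fit$id.med),
            class = "pam_clusters")
}

#' @export
tidy.pam_clusters <- function(x, ...) x$assignments

#' @export
glance.pam_clusters <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$assignments),
         fraction_min = min(x$fractions), fraction_max = max(x$fractions))
}

#' @export
print.pam_clusters <- function(x, ...) {
  cat(sprintf("<pam_clusters> k=%d, fractions: %s\n", x$k,
              paste(sprintf("%.3f", x$fractions), collapse = ", ")))
  print(x$medoids)
  invisible(x)
}

#' Quantile-quantile regression between a reporter and a control sample
#'
#' Computes matched quantiles of the two samples on a common probability grid
#' and regresses sample quantiles on control quantiles over the window
#' `[q_lo, q_hi]`. A slope near one over a low-expression window indicates
#' the reporter's lower tail tracks the autofluorescence control — i.e. no
#' detectable leaky expression — while remaining insensitive to the
#' expressing upper tail.
#'
#' @param sample,control Numeric vectors (each n >= 100).
#' @param q_lo,q_hi Probability window for the regression (defaults 0.10 and
#'   0.25).
#' @param step Probability grid step (default 0.005).
#' @return List of class `qq_fit`: `slope`, `intercept`, `quantiles` tibble
#'   (`prob`, `control_q`, `sample_q`, `in_window`).
#' @export
qq_compare <- function(sample, control, q_lo = 0.10, q_hi = 0.25,
                       step = 0.005) {
  if (length(sample) < 100 || length(control) < 100) {
    abort("need n >= 100 in both samples")
  }
  if (sd(control) == 0) abort("degenerate (constant) control sample")
  probs <- seq(step, 1 - step, by = step)
  qs <- tibble(
    prob = probs,
    control_q = quantile(control, probs, names = FALSE, type = 7),
    sample_q = quantile(sample, probs, names = FALSE, type = 7),
    in_window = probs >= q_lo & probs <= q_hi
  )
  win <- qs[qs$in_window, ]
  fit <- lm(sample_q ~ control_q, data = win)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), quantiles = qs),
            class = "qq_fit")
}

#' @export
tidy.qq_fit <- function(x, ...) x$quantiles

#' @export
glance.qq_fit <- function(x, ...) tibble(slope = x$slope, intercept = x$intercept)

#' @export
print.qq_fit <- function(x, ...) {
  cat(sprintf("<qq_fit> slope %.4g, intercept %.4g over window [%g, %g]\n",
              x$slope, x$intercept,
              min(x$quantiles$prob[x$quantiles$in_window]),
              max(x$quantiles$prob[x$quantiles$in_window])))
  invisible(x)
}

#' FACS-style intensity bin gating from the top
#'
#' Defines bins on empirical quantiles counted from the most intense cell
#' (0% = brightest): the bin `c(lo, hi)` in percent selects ranks
#' `floor(lo*n/100)+1 .. floor(hi*n/100)` of the intensity order statistics,
#' descending, with ties broken by stable ordering. Bins must not overlap.
#'
#' @param intensities Numeric vector.
#' @param bins List of `c(lo, hi)` percent ranges, or a string such as
#'   `"0-2, 5-7, 10-12, 20-25"`.
#' @return Named list of integer index vectors (into `intensities`), names
#'   `"lo-hi%"`.
#' @examples
#' gate_bins(rnorm(1000), list(c(0, 2), c(5, 7)))
#' @export
gate_bins <- function(intensities, bins) {
  if (is.character(bins)) {
    parts <- strsplit(gsub("[% ]", "", bins), ",")[[1]]
    bins <- lapply(strsplit(parts, "-"), as.numeric)
  }
  bins <- lapply(bins, function(b) {
    if (length(b) != 2 || anyNA(b) || b[1] < 0 || b[2] > 100 || b[1] >= b[2]) {
      abort("each bin must be c(lo, hi) percent with 0 <= lo < hi <= 100")
    }
    b
  })
  ord <- order(bins_lo <- vapply(bins, `[`, numeric(1), 1))
  sorted <- bins[ord]
  for (i in seq_along(sorted)[-1]) {
    if (sorted[[i]][1] < sorted[[i - 1]][2]) abort("bins must not overlap")
  }
  n <- length(intensities)
  rank_desc <- order(-intensities)  # stable: ties by original position
  out <- lapply(bins, function(b) {
    lo_idx <- floor(b[1] * n / 100) + 1
    hi_idx <- min(floor(b[2] * n / 100), n)
    if (hi_idx < lo_idx) return(integer(0))
    rank_desc[lo_idx:hi_idx]
  })
  names(out) <- vapply(bins, function(b) sprintf("%g-%g%%", b[1], b[2]),
                       character(1))
  out
}
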