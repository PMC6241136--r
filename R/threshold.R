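#' Medcouple-vs-threshold scan for MitoTracker petite exclusion
#'
#' For each candidate intensity threshold, computes the medcouple of the
#' growth rates of colonies at or above the threshold. Over a wide grid the
#' curve shows three phases: rising while the threshold sweeps through petite
#' intensities (removing the petite left tail), a plateau between the two
#' intensity classes, and rising again once the threshold cuts into
#' non-petites (whose intensity correlates positively with growth). The
#' plateau identifies thresholds that remove petites without biasing against
#' slow-growing non-petites.
#'
#' @param data Data frame of per-colony measurements.
#' @param intensity,rate Bare column names of MitoTracker intensity (a.u.)
#'   and growth rate (h^-1).
#' @param n_grid Number of evenly spaced candidate thresholds (default 200).
#' @param grid Optional explicit ascending threshold grid (overrides
#'   `n_grid`/`probs`).
#' @param probs Intensity quantiles bounding the default grid.
#' @param min_n Minimum retained colonies for a grid point to be evaluated;
#'   sparser points get `NA` (default 100).
#' @return A tibble of class `threshold_scan`: `threshold`, `n_retained`,
#'   `mc`. Pipe into [loess_smooth()] then [detect_plateau()].
#' @export
threshold_scan <- function(data, intensity = mito_intensity, rate = rate,
                           n_grid = 200, grid = NULL,
                           probs = c(0.005, 0.995), min_n = 100) {
  x <- eval_tidy(enquo(intensity), data)
  r <- eval_tidy(enquo(rate), data)
  if (length(x) != length(r)) abort("intensity and rate differ in length")
  ok <- is.finite(x) & is.finite(r)
  x <- x[ok]; r <- r[ok]
  if (is.null(grid)) {
    q <- quantile(x, probs, names = FALSE)
    grid <- seq(q[1], q[2], length.out = n_grid)
  }
  if (is.unsorted(grid)) abort("grid must be ascending")
  res <- purrr::map(grid, function(t) {
    keep <- r[x >= t]
    mc <- if (length(keep) >= max(min_n, 3)) medcouple_value(keep) else NA_real_
    tibble(threshold = t, n_retained = length(keep), mc = mc)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "min_n") <- min_n
  class(out) <- c("threshold_scan", class(out))
  out
}

#' Loess-smooth a threshold scan
#'
#' Locally weighted quadratic regression of the medcouple on the threshold,
#' evaluated at the grid points. Smoothing suppresses the sampling noise of
#' individual medcouples before plateau detection.
#'
#' @param scan A [threshold_scan()] result.
#' @param span Loess span (default 0.4).
#' @return The scan with an `mc_smooth` column added.
#' @export
loess_smooth <- function(scan, span = 0.4) {
  ok <- !is.na(scan$mc)
  if (sum(ok) < 10) abort("need >= 10 non-missing scan points to smooth")
  fit <- loess(mc ~ threshold, data = scan[ok, ], span = span, degree = 2,
               control = stats::loess.control(surface = "direct"))
  scan$mc_smooth <- NA_real_
  scan$mc_smooth[ok] <- predict(fit, newdata = scan$threshold[ok])
  attr(scan, "span") <- span
  scan
}

#' Detect the plateau of a smoothed threshold scan
#'
#' The plateau is the longest contiguous run of grid points whose absolute
#' local slope (central differences of the smoothed curve) is at most
#' `flat_frac` times the median absolute slope of the points outside the
#' candidate run. Because the reference slope depends on the run, the rule is
#' applied iteratively until the run stabilises.
#'
#' @param scan A scan with an `mc_smooth` column (a scan without one is
#'   smoothed with the default span first).
#' @param flat_frac Slope-ratio defining "flat" (default 0.25).
#' @param min_run Minimum run length to accept (default 3).
#' @param rise_min Minimum smoothed-medcouple rise required before and after
#'   a run for it to count as a between-phases plateau (default 0.02); runs
#'   without such rises (e.g. the saturated top of the scan) are used only
#'   when no run qualifies, which is the correct reading of a globally flat
#'   curve.
#' @param max_iter Iteration cap.
#' @return List of class `mc_plateau`: `lo`, `hi` (threshold units), `idx`
#'   (grid indices), `iterations`.
#' @export
detect_plateau <- function(scan, flat_frac = 0.25, min_run = 3,
                           rise_min = 0.02, max_iter = 25) {
  if (is.null(scan$mc_smooth)) scan <- loess_smooth(scan)
  ok <- which(!is.na(scan$mc_smooth))
  if (length(ok) < 10) abort("need >= 10 smoothed points")
  x <- scan$threshold[ok]
  y <- scan$mc_smooth[ok]
  m <- length(ok)
  slope <- numeric(m)
  slope[1] <- (y[2] - y[1]) / (x[2] - x[1])
  slope[m] <- (y[m] - y[m - 1]) / (x[m] - x[m - 1])
  if (m > 2) {
    i <- 2:(m - 1)
    slope[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  abs_s <- abs(slope)

  run <- integer(0)
  for (iter in seq_len(max_iter)) {
    outside <- setdiff(seq_len(m), run)
    ref <- median(abs_s[outside])
    flat <- abs_s <= flat_frac * ref
    new_run <- pick_plateau_run(flat, y, min_run, rise_min)
    if (length(new_run) < min_run) abort("no plateau: no flat run of sufficient length")
    if (identical(new_run, run)) break
    run <- new_run
  }
  structure(list(lo = x[run[1]], hi = x[run[length(run)]],
                 idx = ok[run], iterations = iter),
            class = "mc_plateau")
}

# Candidate flat runs of sufficient length; prefer the longest run that is a
# true between-phases plateau (the curve rises by >= rise_min both before
# and after it). The saturated top of a scan is flat but nothing rises after
# it, so it only qualifies as a fallback when no run passes the rise test
# (e.g. a globally flat curve).
pick_plateau_run <- function(flat, y, min_run, rise_min) {
  r <- rle(flat)
  if (!any(r$values)) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_run)
  if (length(keep) == 0) {
    keep <- which(r$values)  # fall through to the length check in the caller
  }
  runs <- lapply(keep, function(k) starts[k]:ends[k])
  rises <- vapply(runs, function(idx) {
    s <- idx[1]; e <- idx[length(idx)]
    before <- if (s > 1) y[s] - min(y[1:(s - 1)]) else 0
    after <- if (e < length(y)) max(y[(e + 1):length(y)]) - y[e] else 0
    before >= rise_min && after >= rise_min
  }, logical(1))
  pool <- if (any(rises)) runs[rises] else runs
  pool[[which.max(lengths(pool))]]
}

#' Select the working threshold from a plateau
#'
#' The threshold is set at the centre of the plateau: `(lo + hi) / 2`.
#'
#' @param plateau An [detect_plateau()] result or a numeric `c(lo, hi)`.
#' @return The selected threshold (intensity a.u.).
#' @examples
#' select_threshold(c(0.01360, 0.01695))  # 0.015275
#' @export
select_threshold <- function(plateau) {
  if (inherits(plateau, "mc_plateau")) plateau <- c(plateau$lo, plateau$hi)
  if (length(plateau) != 2 || plateau[1] > plateau[2]) {
    abort("plateau must be c(lo, hi) with lo <= hi")
  }
  (plateau[1] + plateau[2]) / 2
}

#' Combine per-strain thresholds into a replicate-wide threshold
#'
#' When several strains or conditions share an experimental replicate, each
#' gets its own scan-derived threshold and the replicate uses their
#' arithmetic mean.
#'
#' @param thresholds Numeric vector of per-strain thresholds (>= 1).
#' @return The common threshold.
#' @export
common_threshold <- function(thresholds) {
  if (length(thresholds) < 1 || any(!is.finite(thresholds))) {
    abort("need at least one finite threshold")
  }
  mean(thresholds)
}

#' Filter a population at a MitoTracker threshold
#'
#' Retains colonies with intensity at or above `scale * threshold` (colonies
#' exactly at the boundary are kept). `scale` values of 0.9 and 1.1 support
#' the robustness re-analysis around the selected threshold. The exclusion
#' report travels as an attribute; retrieve it with [exclusion_report()].
#'
#' @param pop Population tibble.
#' @param threshold Selected intensity threshold (a.u.).
#' @param scale Multiplier on the threshold (commonly 0.9, 1.0 or 1.1).
#' @param intensity Bare column name of the intensity (default
#'   `mito_intensity`).
#' @return The retained rows, with attribute `exclusion_report`.
#' @export
apply_threshold <- function(pop, threshold, scale = 1,
                            intensity = mito_intensity) {
  x <- eval_tidy(enquo(intensity), pop)
  eff <- scale * threshold
  keep <- x >= eff
  out <- pop[keep, ]
  attr(out, "exclusion_report") <- tibble(
    threshold = threshold, scale = scale, effective_threshold = eff,
    n_total = length(keep), n_retained = sum(keep),
    n_excluded = sum(!keep), frac_excluded = mean(!keep)
  )
  out
}

#' @rdname apply_threshold
#' @param x A filtered population from [apply_threshold()].
#' @export
exclusion_report <- function(x) attr(x, "exclusion_report")

#' One-call threshold selection: scan, smooth, plateau, midpoint
#'
#' @inheritParams threshold_scan
#' @param span Loess span.
#' @param flat_frac,min_run Plateau-detection parameters.
#' @return List: `scan` (smoothed), `plateau`, `threshold`.
#' @export
select_mito_threshold <- function(data, intensity = mito_intensity,
                                  rate = rate, n_grid = 200, min_n = 100,
                                  probs = c(0.005, 0.995), span = 0.4,
                                  flat_frac = 0.25, min_run = 3) {
  scan <- threshold_scan(data, {{ intensity }}, {{ rate }}, n_grid = n_grid,
                         probs = probs, min_n = min_n)
  scan <- loess_smooth(scan, span = span)
  plateau <- detect_plateau(scan, flat_frac = flat_frac, min_run = min_run)
  list(scan = scan, plateau = plateau, threshold = select_threshold(plateau))
}

#' @export
print.mc_plateau <- function(x, ...) {
  cat(sprintf("<mc_plateau> [%g, %g] (midpoint %g, %d grid points)\n",
              x$lo, x$hi, (x$lo + x$hi) / 2, length(x$idx)))
  invisible(x)
}
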