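#' Estimate the total petite frequency from threshold-crossing fractions
#'
#' MitoTracker thresholding is imperfect: a fraction `a` of true petites
#' (measured on a reference rho0 population) exceeds the threshold, so the
#' observed below-threshold fraction `b` of the focal population
#' underestimates the petite frequency. Assuming the focal population's
#' petites cross the threshold at the reference rate, the total petite
#' frequency `p` solves `p * (1 - a) = b`.
#'
#' @param b Fraction of the focal population below the threshold, in \[0, 1).
#' @param a Fraction of reference petites above the threshold, in \[0, 1).
#' @return `p_total = b / (1 - a)`.
#' @examples
#' estimate_total_petite_frequency(0.1245, 0.2179)  # 0.1592
#' @export
estimate_total_petite_frequency <- function(b, a) {
  check_proportion(b, "b")
  check_proportion(a, "a")
  if (a >= 1) abort("a = 1 carries no information (all petites cross the threshold)")
  if (b >= 1) abort("b must be < 1")
  b / (1 - a)
}

#' Estimate petite contamination of the after-threshold set
#'
#' Of the `p_total * a` petites that cross the threshold, the contamination of
#' the retained (above-threshold) set of size `1 - b` is
#' `c = (p_total * a) / (1 - b)`.
#'
#' @param p_total Total petite frequency (e.g. from
#'   [estimate_total_petite_frequency()]).
#' @inheritParams estimate_total_petite_frequency
#' @return The contamination fraction `c`.
#' @examples
#' p <- estimate_total_petite_frequency(0.1245, 0.2179)
#' estimate_contamination(p, 0.2179, 0.1245)  # 0.0396
#' @export
estimate_contamination <- function(p_total, a, b) {
  check_proportion(p_total, "p_total")
  check_proportion(a, "a")
  check_proportion(b, "b")
  if (b >= 1) abort("b = 1 leaves no after-threshold set")
  (p_total * a) / (1 - b)
}

#' Both petite estimates as one tidy row
#'
#' @inheritParams estimate_total_petite_frequency
#' @return One-row tibble: `b`, `a`, `p_total`, `contamination`.
#' @export
petite_contamination <- function(b, a) {
  p <- estimate_total_petite_frequency(b, a)
  tibble(b = b, a = a, p_total = p,
         contamination = estimate_contamination(p, a, b))
}

#' Worst-case petite spike-in simulation
#'
#' Repeatedly mixes reference petite colonies into a wild-type population at a
#' target final proportion, re-runs the full threshold pipeline
#' (scan, smooth, plateau, midpoint) on each mixture, and re-estimates the
#' contamination of the after-threshold set. Because added petites drag the
#' selected threshold upward, recomputing the threshold per mixture
#' (`recompute_threshold = TRUE`, the default) yields less contamination than
#' freezing the original threshold; the frozen mode supports that paired
#' comparison.
#'
#' @param wt_pop,petite_pop Population tibbles with intensity and rate
#'   columns; `petite_pop` is sampled with replacement.
#' @param target_petite_frac Final petite proportion of each mixture,
#'   in (0, 1).
#' @param n_samplings Number of random mixtures (default 100).
#' @param seed Integer seed; each sampling gets a derived sub-seed.
#' @param recompute_threshold Recompute the threshold on each mixture, or
#'   reuse `frozen_threshold`.
#' @param frozen_threshold Threshold used when `recompute_threshold = FALSE`
#'   (defaults to the wild-type pipeline threshold).
#' @param intensity,rate Bare column names.
#' @param ... Passed to [select_mito_threshold()].
#' @return List of class `spike_in`: `$samplings` (per-sampling tibble with
#'   `threshold`, `b`, `a`, `p_total`, `contamination`, `ok`), `$mean`, `$sd`
#'   (over successful samplings), `$n_failed` (plateau failures, skipped).
#' @export
spike_in_simulation <- function(wt_pop, petite_pop, target_petite_frac = 0.38,
                                n_samplings = 100, seed = 1,
                                recompute_threshold = TRUE,
                                frozen_threshold = NULL,
                                intensity = mito_intensity, rate = rate, ...) {
  if (target_petite_frac < 0 || target_petite_frac >= 1) {
    abort("target_petite_frac must be in [0, 1)")
  }
  wt <- tibble(
    intensity = eval_tidy(enquo(intensity), wt_pop),
    rate = eval_tidy(enquo(rate), wt_pop)
  )
  pet <- tibble(
    intensity = eval_tidy(enquo(intensity), petite_pop),
    rate = eval_tidy(enquo(rate), petite_pop)
  )
  n_wt <- nrow(wt)
  # n_add petites so that petites make up the target fraction of the mixture
  n_add <- round(target_petite_frac * n_wt / (1 - target_petite_frac))
  if (!recompute_threshold && is.null(frozen_threshold)) {
    frozen_threshold <- select_mito_threshold(wt, intensity, rate, ...)$threshold
  }
  seeds <- derive_seeds(seed, n_samplings)
  rows <- purrr::map(seq_len(n_samplings), function(s) {
    mix <- with_seed_if(seeds[[s]], {
      dplyr::bind_rows(wt, pet[sample.int(nrow(pet), n_add, replace = TRUE), ])
    })
    thr <- if (recompute_threshold) {
      tryCatch(select_mito_threshold(mix, intensity, rate, ...)$threshold,
               error = function(e) NA_real_)
    } else frozen_threshold
    if (is.na(thr)) {
      return(tibble(sampling = s, threshold = NA_real_, b = NA_real_,
                    a = NA_real_, p_total = NA_real_,
                    contamination = NA_real_, ok = FALSE))
    }
    b <- mean(mix$intensity < thr)
    a <- mean(pet$intensity >= thr)
    est <- petite_contamination(b, a)
    tibble(sampling = s, threshold = thr, b = b, a = a,
           p_total = est$p_total, contamination = est$contamination, ok = TRUE)
  })
  samplings <- dplyr::bind_rows(rows)
  good <- samplings$contamination[samplings$ok]
  structure(list(
    samplings = samplings,
    mean = mean(good), sd = if (length(good) > 1) sd(good) else 0,
    n_failed = sum(!samplings$ok)
  ), class = "spike_in")
}

#' @export
print.spike_in <- function(x, ...) {
  cat(sprintf(
    "<spike_in> contamination mean %.4g, sd %.4g over %d samplings (%d failed)\n",
    x$mean, x$sd, sum(x$samplings$ok), x$n_failed))
  invisible(x)
}

#' Petite frequency from red/white colony counts
#'
#' TTC staining turns respiration-competent colonies red; petites stay white.
#' The frequency is `white / (white + red)` with an exact binomial confidence
#' interval.
#'
#' @param n_red,n_white Colony counts (red = respiring, white = petite).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `n_red`, `n_white`, `frequency`, `conf_lo`,
#'   `conf_hi`.
#' @examples
#' petite_frequency_from_counts(85, 15)  # 0.15
#' @export
petite_frequency_from_counts <- function(n_red, n_white, conf_level = 0.95) {
  if (n_red < 0 || n_white < 0) abort("counts must be non-negative")
  total <- n_red + n_white
  if (total == 0) abort("zero total colony count")
  bt <- binom.test(n_white, total, conf.level = conf_level)
  tibble(n_red = n_red, n_white = n_white, frequency = n_white / total,
         conf_lo = bt$conf.int[1], conf_hi = bt$conf.int[2])
}

#' Paired test of petite frequencies on the arcsine scale
#'
#' Paired t-test on variance-stabilised frequencies, `asin(sqrt(f))`,
#' appropriate for comparing petite frequencies between paired samples (e.g.
#' high- vs low-reporter FACS fractions from the same replicate).
#'
#' @param f1,f2 Paired frequency vectors in \[0, 1\].
#' @return One-row tibble: `estimate` (mean transformed difference),
#'   `statistic`, `df`, `p_value`.
#' @export
paired_frequency_test <- function(f1, f2) {
  if (length(f1) != length(f2)) abort("pairs must be aligned")
  if (any(f1 < 0 | f1 > 1 | f2 < 0 | f2 > 1)) {
    abort("frequencies must be in [0, 1]")
  }
  d <- asin(sqrt(f1)) - asin(sqrt(f2))
  if (sd(d) == 0) {
    # degenerate paired differences: identical pairs carry no evidence
    if (mean(d) != 0) abort("constant nonzero paired differences; t-test undefined")
    return(tibble(estimate = 0, statistic = 0, df = length(d) - 1, p_value = 1))
  }
  tt <- t.test(asin(sqrt(f1)), asin(sqrt(f2)), paired = TRUE)
  tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value)
}
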