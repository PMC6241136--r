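#' Fit an exponential growth rate to one colony's area series
#'
#' Microcolony areas grow exponentially after an initial lag, so the growth
#' rate (h^-1) is the slope of `ln(area)` on time. The fit searches every
#' contiguous window of at least `min_points` time points and keeps the
#' window maximising R^2 (ties broken toward the longest, then the earliest,
#' window), which accommodates a flat lag phase at the start of the series
#' without modelling it explicitly. No colony is silently dropped: quality
#' problems are reported through `flag` and filtering is the caller's
#' decision.
#'
#' @param areas Strictly positive areas.
#' @param times Strictly increasing observation times (h).
#' @param min_points Minimum window length (default 4).
#' @param min_r2 R^2 below which the fit is flagged `poor_fit` (default 0.9).
#' @return One-row tibble: `rate` (h^-1), `lag_end` (h, window start),
#'   `win_start`, `win_end` (1-based indices), `r_squared`, `n_points_used`,
#'   `flag` (`ok`, `too_few_points`, `poor_fit`).
#' @examples
#' fit_growth_rate(c(100, 200, 400, 800, 1600), 0:4)  # rate = log(2)
#' @export
fit_growth_rate <- function(areas, times = seq_along(areas) - 1,
                            min_points = 4, min_r2 = 0.9) {
  if (length(areas) != length(times)) abort("areas and times differ in length")
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    abort("areas must be strictly positive and finite")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("times must be strictly increasing")
  }
  if (length(areas) < min_points) {
    return(growth_fit_row(NA_real_, NA_real_, NA_integer_, NA_integer_,
                          NA_real_, length(areas), "too_few_points"))
  }
  wins <- window_index(length(areas), min_points)
  stats <- window_stats(matrix(log(areas), nrow = 1), times, wins)
  pick <- pick_window(stats$r2[1, ], wins)
  w <- wins[pick$idx, ]
  r2 <- stats$r2[1, pick$idx]
  flag <- if (is.na(r2) || r2 < min_r2) "poor_fit" else "ok"
  growth_fit_row(stats$slope[1, pick$idx], times[w[1]], w[1], w[2], r2,
                 w[2] - w[1] + 1L, flag)
}

growth_fit_row <- function(rate, lag_end, ws, we, r2, n, flag) {
  tibble(rate = rate, lag_end = lag_end, win_start = ws, win_end = we,
         r_squared = r2, n_points_used = as.integer(n), flag = flag)
}

# all contiguous windows of length >= min_points, as (start, end) rows
window_index <- function(n, min_points) {
  out <- list()
  for (s in seq_len(n - min_points + 1)) {
    for (e in seq(s + min_points - 1, n)) out[[length(out) + 1]] <- c(s, e)
  }
  do.call(rbind, out)
}

# least-squares slope and R^2 of each window, vectorised over rows of Y
window_stats <- function(Y, times, wins) {
  n <- nrow(Y)
  W <- nrow(wins)
  slope <- r2 <- matrix(NA_real_, n, W)
  for (w in seq_len(W)) {
    idx <- wins[w, 1]:wins[w, 2]
    tc <- times[idx] - mean(times[idx])
    sxx <- sum(tc^2)
    Yw <- Y[, idx, drop = FALSE]
    b <- (Yw %*% tc) / sxx
    ssy <- rowSums((Yw - rowMeans(Yw))^2)
    slope[, w] <- b
    r2w <- as.vector(b)^2 * sxx / ssy
    r2w[ssy == 0] <- NA_real_  # flat window: slope 0, R^2 undefined
    slope[ssy == 0, w] <- 0
    r2[, w] <- r2w
  }
  list(slope = slope, r2 = r2)
}

# best window for one colony: max R^2, ties (within 1e-9) -> longest,
# then earliest; all-undefined R^2 -> longest earliest window
pick_window <- function(r2, wins) {
  len <- wins[, 2] - wins[, 1] + 1L
  if (all(is.na(r2))) {
    idx <- order(-len, wins[, 1])[1]
    return(list(idx = idx))
  }
  best <- max(r2, na.rm = TRUE)
  cand <- which(!is.na(r2) & r2 >= best - 1e-9)
  list(idx = cand[order(-len[cand], wins[cand, 1])[1]])
}

#' Fit growth rates for a whole population
#'
#' Row-wise [fit_growth_rate()] over the `area_h<t>` columns, vectorised.
#' Counts of each quality flag are reported as a message; no row is dropped.
#'
#' @param pop Population tibble with `area_h<t>` columns (hour parsed from
#'   the name).
#' @inheritParams fit_growth_rate
#' @param quiet Suppress the flag-count message.
#' @return `pop` with columns `rate`, `lag_end`, `win_start`, `win_end`,
#'   `r_squared`, `n_points_used`, `flag` appended.
#' @export
fit_population <- function(pop, min_points = 4, min_r2 = 0.9, quiet = FALSE) {
  area_cols <- grep("^area_h[0-9]+$", names(pop), value = TRUE)
  if (length(area_cols) == 0) abort("no area_h<t> columns found")
  times <- as.numeric(sub("^area_h", "", area_cols))
  ord <- order(times)
  area_cols <- area_cols[ord]
  times <- times[ord]
  if (nrow(pop) == 0) {
    out <- dplyr::bind_cols(pop, growth_fit_row(numeric(0), numeric(0),
      integer(0), integer(0), numeric(0), integer(0), character(0)))
    return(out)
  }
  A <- as.matrix(pop[, area_cols])
  if (any(!is.finite(A)) || any(A <= 0)) {
    bad <- which(rowSums(!is.finite(A) | A <= 0) > 0)[1]
    abort(sprintf("non-positive or missing area in row %d", bad))
  }
  if (length(times) < min_points) {
    fits <- growth_fit_row(NA_real_, NA_real_, NA_integer_, NA_integer_,
                           NA_real_, length(times), "too_few_points")[
                             rep(1, nrow(pop)), ]
  } else {
    wins <- window_index(length(times), min_points)
    stats <- window_stats(log(A), times, wins)
    fits <- purrr::map(seq_len(nrow(pop)), function(i) {
      pick <- pick_window(stats$r2[i, ], wins)
      w <- wins[pick$idx, ]
      r2 <- stats$r2[i, pick$idx]
      flag <- if (is.na(r2) || r2 < min_r2) "poor_fit" else "ok"
      growth_fit_row(stats$slope[i, pick$idx], times[w[1]], w[1], w[2], r2,
                     w[2] - w[1] + 1L, flag)
    })
    fits <- dplyr::bind_rows(fits)
  }
  if (!quiet) {
    counts <- table(fits$flag)
    rlang::inform(sprintf("growth fits: %s",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  }
  dplyr::bind_cols(as_tibble(pop), fits)
}

#' Partition growth-rate variance into plate/well/field components
#'
#' Restricted-maximum-likelihood mixed model (via \pkg{lme4}) with random
#' intercepts for plate, well-within-plate and field-within-well, optionally
#' a fixed strain effect. Quantifies how much apparent growth-rate
#' heterogeneity is attributable to technical structure rather than cell
#' state. Random factors with fewer than two levels are dropped with a
#' warning rather than failing.
#'
#' @param data Data frame of fitted rates and labels.
#' @param rate,plate,well,field Bare column names.
#' @param strain Optional bare column name of a fixed-effect grouping.
#' @return Tibble: `component`, `variance`, `sd`, `proportion`.
#' @export
partition_variance <- function(data, rate, plate, well, field, strain = NULL) {
  df <- tibble(
    .rate = eval_tidy(enquo(rate), data),
    .plate = as.character(eval_tidy(enquo(plate), data)),
    .well = as.character(eval_tidy(enquo(well), data)),
    .field = as.character(eval_tidy(enquo(field), data))
  )
  strain_q <- enquo(strain)
  has_strain <- !rlang::quo_is_null(strain_q)
  if (has_strain) df$.strain <- as.character(eval_tidy(strain_q, data))
  df$.well_id <- paste(df$.plate, df$.well, sep = ":")
  df$.field_id <- paste(df$.well_id, df$.field, sep = ":")

  terms <- c(plate = ".plate", well = ".well_id", field = ".field_id")
  keep <- vapply(terms, function(v) length(unique(df[[v]])) >= 2, logical(1))
  if (any(!keep)) {
    warn(sprintf("dropping random component(s) with < 2 levels: %s",
                 paste(names(terms)[!keep], collapse = ", ")))
  }
  terms <- terms[keep]
  if (length(terms) == 0) abort("no random factor has >= 2 levels")
  fixed <- if (has_strain) ".rate ~ .strain" else ".rate ~ 1"
  form <- stats::as.formula(paste(
    fixed, "+", paste(sprintf("(1 | %s)", terms), collapse = " + ")))
  fit <- lme4::lmer(form, data = df, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- ifelse(vc$grp == "Residual", "residual",
                 names(terms)[match(vc$grp, terms)])
  out <- tibble(component = comp, variance = vc$vcov, sd = vc$sdcor)
  out$proportion <- out$variance / sum(out$variance)
  out
}
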