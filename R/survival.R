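#' Match pre- and post-heat-shock colonies across a global stage shift
#'
#' Removing and returning the microplate translates all coordinates by an
#' unknown global shift. The shift is estimated as the component-wise median
#' of displacement vectors over provisional mutual-nearest-neighbour pairs
#' (robust even when most provisional pairs are wrong, because mismatch
#' errors are isotropic with median near zero); colonies are then re-matched
#' by mutual nearest neighbour within `max_radius` after shift removal, and
#' the shift is re-estimated from the final matched pairs. Unmatched colonies
#' on either side are reported, never silently dropped.
#'
#' @param pre,post Tibbles with `colony_id`, `centroid_x`, `centroid_y`
#'   (>= 10 rows each).
#' @param max_radius Maximum residual distance (px) for a final match.
#' @return Object of class `lineage_match`: `pairs` tibble (`pre_id`,
#'   `post_id`, `residual` px), `shift` (named length-2 vector),
#'   `unmatched_pre`, `unmatched_post` (character ids).
#' @export
match_lineages <- function(pre, post, max_radius = 5) {
  for (nm in c("colony_id", "centroid_x", "centroid_y")) {
    if (!nm %in% names(pre) || !nm %in% names(post)) {
      abort(sprintf("pre and post must both have column `%s`", nm))
    }
  }
  if (nrow(pre) < 10 || nrow(post) < 10) abort("need >= 10 centroids per phase")
  A <- cbind(pre$centroid_x, pre$centroid_y)
  B <- cbind(post$centroid_x, post$centroid_y)

  # Coarse translation from the mode of the displacement-vector distribution:
  # when the shift exceeds the nearest-neighbour spacing, raw mutual-NN pairs
  # are dominated by wrong partners whose displacements cluster at zero, so
  # the true shift must be located first as the densest displacement bin.
  coarse <- coarse_shift(A, B)
  prov <- mutual_nn(A, sweep(B, 2, coarse))
  if (nrow(prov) == 0) abort("shift estimation failed: no provisional pairs")
  shift <- c(
    x = median(B[prov[, 2], 1] - A[prov[, 1], 1]),
    y = median(B[prov[, 2], 2] - A[prov[, 1], 2])
  )

  B_shifted <- sweep(B, 2, shift)
  final <- mutual_nn(A, B_shifted)
  resid <- sqrt(rowSums((B_shifted[final[, 2], , drop = FALSE] -
                         A[final[, 1], , drop = FALSE])^2))
  keep <- resid <= max_radius
  final <- final[keep, , drop = FALSE]
  resid <- resid[keep]

  if (nrow(final) > 0) {
    shift <- c(
      x = median(B[final[, 2], 1] - A[final[, 1], 1]),
      y = median(B[final[, 2], 2] - A[final[, 1], 2])
    )
  }
  pairs <- tibble(pre_id = pre$colony_id[final[, 1]],
                  post_id = post$colony_id[final[, 2]],
                  residual = resid)
  structure(list(
    pairs = pairs, shift = shift,
    unmatched_pre = setdiff(pre$colony_id, pairs$pre_id),
    unmatched_post = setdiff(post$colony_id, pairs$post_id)
  ), class = "lineage_match")
}

# Mode of the displacement-vector histogram between a subsample of A and all
# of B, refined by the median of displacements near the peak bin.
coarse_shift <- function(A, B, n_sample = 400L, bin = 10) {
  idx <- if (nrow(A) > n_sample) {
    round(seq(1, nrow(A), length.out = n_sample))
  } else seq_len(nrow(A))
  dx <- as.vector(outer(B[, 1], A[idx, 1], "-"))
  dy <- as.vector(outer(B[, 2], A[idx, 2], "-"))
  bx <- floor(dx / bin)
  by <- floor(dy / bin)
  key <- paste(bx, by)
  peak <- names(which.max(table(key)))
  near <- key == peak
  c(median(dx[near]), median(dy[near]))
}

# mutual nearest neighbours between point sets (rows), chunked to bound memory
mutual_nn <- function(A, B, chunk = 512L) {
  nn_ab <- nn_index(A, B, chunk)   # for each row of A, nearest row of B
  nn_ba <- nn_index(B, A, chunk)
  mutual <- which(nn_ba[nn_ab] == seq_len(nrow(A)))
  cbind(pre = mutual, post = nn_ab[mutual])
}

nn_index <- function(X, Y, chunk) {
  n <- nrow(X)
  out <- integer(n)
  y1 <- Y[, 1]; y2 <- Y[, 2]
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    d2 <- outer(X[s:e, 1], y1, "-")^2 + outer(X[s:e, 2], y2, "-")^2
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' @export
print.lineage_match <- function(x, ...) {
  cat(sprintf("<lineage_match> %d pairs, shift (%.2f, %.2f); unmatched pre %d, post %d\n",
              nrow(x$pairs), x$shift[["x"]], x$shift[["y"]],
              length(x$unmatched_pre), length(x$unmatched_post)))
  invisible(x)
}

#' Call colony survival from post-shock area growth
#'
#' A colony is alive if its area at least doubles during the post-shock
#' window: `fold_change = max(post areas) / final pre-shock area`, alive iff
#' `fold_change >= 2` (boundary inclusive).
#'
#' @param pre_final_area Final pre-shock area(s), positive.
#' @param post_area_max Maximum post-shock area(s); `NA` (lost colony) yields
#'   an `NA` call.
#' @return Tibble: `fold_change`, `alive`.
#' @examples
#' call_survival(100, c(210, 150, 200))
#' @export
call_survival <- function(pre_final_area, post_area_max) {
  if (any(pre_final_area <= 0, na.rm = TRUE) ||
      any(post_area_max <= 0, na.rm = TRUE)) {
    abort("areas must be positive")
  }
  fold <- post_area_max / pre_final_area
  tibble(fold_change = fold, alive = fold >= 2)
}

#' Logistic regression of survival on a single-cell covariate
#'
#' Maximum-likelihood binary logistic fit of the alive/dead call on a
#' pre-shock covariate (growth rate or reporter intensity), with a pointwise
#' 95% band from the delta method on the linear predictor. A negative slope
#' on growth rate is the signature of growth-correlated bet-hedging: slower
#' colonies survive acute stress more often.
#'
#' @param data Per-colony data frame.
#' @param x Bare column name of the covariate.
#' @param alive Bare column name of the logical outcome.
#' @param n_grid Prediction grid size.
#' @return Object of class `logistic_survival` with `tidy()`, `glance()` and
#'   `autoplot()` methods; coefficients in `$coef`, SEs in `$se`.
#' @export
logistic_survival <- function(data, x = rate, alive = alive, n_grid = 100) {
  df <- tibble(
    x = eval_tidy(enquo(x), data),
    alive = as.logical(eval_tidy(enquo(alive), data))
  )
  df <- df[complete.cases(df), ]
  if (nrow(df) < 50) abort("need n >= 50 colonies")
  if (length(unique(df$alive)) < 2) {
    abort("both outcome classes must be present")
  }
  fit <- withCallingHandlers(
    glm(alive ~ x, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        abort("perfect (or quasi-perfect) separation: logistic fit unstable")
      }
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged || any(abs(coef(fit)) > 1e3)) {
    abort("perfect (or quasi-perfect) separation: logistic fit unstable")
  }
  sm <- summary(fit)
  grid <- tibble(x = seq(min(df$x), max(df$x), length.out = n_grid))
  pr <- predict(fit, newdata = grid, type = "link", se.fit = TRUE)
  curve <- tibble(x = grid$x, fit = plogis(pr$fit),
                  conf_lo = plogis(pr$fit - 1.96 * pr$se.fit),
                  conf_hi = plogis(pr$fit + 1.96 * pr$se.fit))
  structure(list(fit = fit, coef = coef(fit),
                 se = sm$coefficients[, "Std. Error"],
                 curve = curve, data = df, n = nrow(df)),
            class = "logistic_survival")
}

#' @export
tidy.logistic_survival <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, "Estimate"],
         std_error = sm[, "Std. Error"], statistic = sm[, "z value"],
         p_value = sm[, "Pr(>|z|)"])
}

#' @export
glance.logistic_survival <- function(x, ...) {
  tibble(n = x$n, intercept = x$coef[[1]], slope = x$coef[[2]],
         slope_se = x$se[[2]], deviance = x$fit$deviance,
         aic = x$fit$aic)
}

#' @export
autoplot.logistic_survival <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_lo,
                                      ymax = .data$conf_hi), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::labs(x = "covariate", y = "survival probability")
}

#' Bulk survival rate from colony counts
#'
#' Plating assay: survival is the ratio of colonies surviving heat shock to
#' colonies of the matched unshocked control, multiplied by the dilution
#' factor between the two platings.
#'
#' @param n_shock,n_control Colony counts; `n_control` must be positive.
#' @param dilution_factor Experiment-specific dilution between shock and
#'   control platings.
#' @return Tibble: counts, dilution factor and `rate`.
#' @examples
#' bulk_survival_rate(10, 400, 2)  # 0.05
#' @export
bulk_survival_rate <- function(n_shock, n_control, dilution_factor = 1) {
  if (any(n_control <= 0)) abort("n_control must be positive")
  if (any(n_shock < 0)) abort("n_shock must be non-negative")
  tibble(n_shock = n_shock, n_control = n_control,
         dilution_factor = dilution_factor,
         rate = n_shock / n_control * dilution_factor)
}

#' Compare bulk survival rates across groups
#'
#' One-way ANOVA on arcsine-transformed (`asin(sqrt(rate))`) replicate
#' survival rates, followed by Tukey honest-significant-difference adjusted
#' all-pairs comparisons. Rates above 1 (possible through the dilution
#' factor) are capped at 1 before the transform.
#'
#' @param data Data frame of replicate-level survival rates.
#' @param rate,group Bare column names.
#' @return List of class `bulk_survival_test`: `omnibus` (one-row tibble
#'   with `statistic`, `df`, `p_value`), `pairs` (per-pair tibble with the
#'   transformed-scale difference and `p_adj`), `group_means` (both scales).
#' @export
compare_bulk_survival <- function(data, rate = rate, group = group) {
  df <- tibble(
    rate = eval_tidy(enquo(rate), data),
    group = factor(eval_tidy(enquo(group), data))
  )
  if (nlevels(df$group) < 2) abort("need >= 2 groups")
  counts <- table(df$group)
  if (any(counts < 2)) {
    abort(sprintf("group(s) with < 2 replicates: %s",
                  paste(names(counts)[counts < 2], collapse = ", ")))
  }
  df$trans <- asin(sqrt(pmin(df$rate, 1)))
  fit <- aov(trans ~ group, data = df)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pairs <- tibble(pair = rownames(tk), diff_transformed = tk[, "diff"],
                  conf_lo = tk[, "lwr"], conf_hi = tk[, "upr"],
                  p_adj = tk[, "p adj"])
  means <- dplyr::summarise(dplyr::group_by(df, .data$group),
                            mean_rate = mean(.data$rate),
                            mean_transformed = mean(.data$trans),
                            .groups = "drop")
  structure(list(
    omnibus = tibble(statistic = sm[["F value"]][1],
                     df = paste(sm[["Df"]], collapse = ", "),
                     p_value = sm[["Pr(>F)"]][1]),
    pairs = pairs, group_means = means
  ), class = "bulk_survival_test")
}

#' @export
tidy.bulk_survival_test <- function(x, ...) x$pairs

#' @export
glance.bulk_survival_test <- function(x, ...) x$omnibus

#' Likelihood-ratio test of a fixed effect in a nested mixed model
#'
#' Fits linear mixed models with random intercepts for biological replicates
#' and technical replicates nested within them (via \pkg{lme4}, maximum
#' likelihood), with and without the fixed grouping effect, and compares
#' them by likelihood-ratio test. With a single technical replicate per
#' biological replicate the technical component is dropped with a warning.
#'
#' @param data Data frame.
#' @param response,group,bio_rep,tech_rep Bare column names.
#' @return One-row tibble: `statistic` (chi-square), `df`, `p_value`.
#' @export
nested_mixed_lrt <- function(data, response, group, bio_rep, tech_rep) {
  df <- tibble(
    y = eval_tidy(enquo(response), data),
    g = factor(eval_tidy(enquo(group), data)),
    bio = as.character(eval_tidy(enquo(bio_rep), data)),
    tech = as.character(eval_tidy(enquo(tech_rep), data))
  )
  if (nlevels(df$g) < 2) abort("need >= 2 levels of the fixed group")
  if (length(unique(df$bio)) < 2) abort("need >= 2 biological replicates")
  df$tech_id <- paste(df$bio, df$tech, sep = ":")
  has_tech <- length(unique(df$tech_id)) > length(unique(df$bio))
  if (!has_tech) {
    warn("single technical replicate per sample; technical component dropped")
  }
  rand <- if (has_tech) "(1 | bio) + (1 | tech_id)" else "(1 | bio)"
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  full <- lme4::lmer(stats::as.formula(paste("y ~ g +", rand)), data = df,
                     REML = FALSE, control = ctrl)
  null <- lme4::lmer(stats::as.formula(paste("y ~ 1 +", rand)), data = df,
                     REML = FALSE, control = ctrl)
  dev <- as.numeric(2 * (logLik(full) - logLik(null)))
  dof <- attr(logLik(full), "df") - attr(logLik(null), "df")
  tibble(statistic = dev, df = dof,
         p_value = pchisq(dev, df = dof, lower.tail = FALSE))
}
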