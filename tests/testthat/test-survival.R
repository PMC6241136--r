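make_centroids <- function(n, seed, field = 2000) {
  set.seed(seed)
  tibble::tibble(colony_id = sprintf("c%04d", seq_len(n)),
                 centroid_x = runif(n, 0, field),
                 centroid_y = runif(n, 0, field))
}

test_that("a pure translation is recovered exactly with full matching", {
  pre <- make_centroids(60, 131)
  post <- pre
  post$colony_id <- sprintf("p%04d", seq_len(60))
  post$centroid_x <- post$centroid_x + 7
  post$centroid_y <- post$centroid_y - 3
  m <- match_lineages(pre, post)
  expect_equal(unname(m$shift), c(7, -3), tolerance = 1e-9)
  expect_equal(nrow(m$pairs), 60)
  expect_length(m$unmatched_pre, 0)
  expect_identical(m$pairs$post_id, sprintf("p%04d", match(m$pairs$pre_id,
                                                           pre$colony_id)))
})

test_that("matching is a bijection and invariant to row order", {
  pre <- make_centroids(200, 132)
  post <- pre
  post$colony_id <- sprintf("p%04d", seq_len(200))
  post$centroid_x <- post$centroid_x + 40
  post$centroid_y <- post$centroid_y + 15
  set.seed(1)
  post$centroid_x <- post$centroid_x + rnorm(200, 0, 0.5)
  post$centroid_y <- post$centroid_y + rnorm(200, 0, 0.5)
  m <- match_lineages(pre, post)
  expect_false(any(duplicated(m$pairs$pre_id)))
  expect_false(any(duplicated(m$pairs$post_id)))
  mp <- match_lineages(pre[sample.int(200), ], post[sample.int(200), ])
  key <- function(p) paste(p$pre_id, p$post_id)[order(p$pre_id)]
  expect_identical(key(mp$pairs), key(m$pairs))
})

test_that("colonies present only pre-shock are reported unmatched", {
  pre <- make_centroids(200, 133)
  keep <- sort(sample.int(200, 180))   # 10% lost after the shock
  post <- pre[keep, ]
  post$colony_id <- sprintf("p%04d", keep)
  post$centroid_x <- post$centroid_x + 25
  post$centroid_y <- post$centroid_y - 12
  m <- match_lineages(pre, post)
  expect_setequal(m$unmatched_pre, pre$colony_id[-keep])
  expect_length(m$unmatched_post, 0)
})

test_that("survival calls honour the inclusive two-fold boundary", {
  calls <- call_survival(100, c(210, 150, 200))
  expect_identical(calls$alive, c(TRUE, FALSE, TRUE))
  expect_equal(calls$fold_change, c(2.1, 1.5, 2))
  expect_error(call_survival(0, 100), "positive")
  na_call <- call_survival(100, NA_real_)
  expect_true(is.na(na_call$alive))
})

test_that("logistic survival fit recovers known coefficients", {
  set.seed(134)
  n <- 5000
  rate <- pmax(rnorm(n, 0.4, 0.1), 0.02)
  alive <- runif(n) < plogis(4 - 10 * rate)
  df <- tibble::tibble(rate = rate, alive = alive)
  fit <- logistic_survival(df)
  g <- glance(fit)
  expect_lt(abs(g$intercept - 4), 3 * fit$se[[1]])
  expect_lt(abs(g$slope + 10), 3 * g$slope_se)
  expect_true(all(diff(fit$curve$fit) < 0))

  expect_error(logistic_survival(tibble::tibble(rate = rate,
                                                alive = TRUE)[1:100, ]),
               "both outcome classes")
  # perfect separation is refused
  sep <- tibble::tibble(rate = c(rnorm(50, 0, 0.1), rnorm(50, 5, 0.1)),
                        alive = rep(c(TRUE, FALSE), each = 50))
  expect_error(logistic_survival(sep), "separation")
})

test_that("slope CI covers zero when survival is independent of the covariate", {
  covered <- vapply(1:60, function(s) {
    set.seed(1400 + s)
    df <- tibble::tibble(rate = rnorm(120, 0.4, 0.1),
                         alive = runif(120) < 0.5)
    g <- glance(logistic_survival(df))
    abs(g$slope) < qnorm(0.975) * g$slope_se
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("bulk survival rate applies the dilution factor", {
  expect_equal(bulk_survival_rate(10, 400, 2)$rate, 0.05)
  expect_equal(bulk_survival_rate(0, 100, 3)$rate, 0)
  expect_equal(bulk_survival_rate(55, 55, 1)$rate, 1)
  expect_error(bulk_survival_rate(5, 0, 1), "positive")
})

test_that("arcsine ANOVA with Tukey HSD separates groups appropriately", {
  # identical group profiles: omnibus p = 1
  df <- tibble::tibble(rate = rep(c(0.1, 0.2, 0.15), 2),
                       group = rep(c("A", "B"), each = 3))
  res <- compare_bulk_survival(df)
  expect_gt(res$omnibus$p_value, 0.99)

  # 100-fold rate difference, 3 replicates, multiplicative noise
  hits <- vapply(1:12, function(s) {
    set.seed(1500 + s)
    df <- tibble::tibble(
      rate = c(0.2 * exp(rnorm(3, 0, 0.2)), 0.002 * exp(rnorm(3, 0, 0.2))),
      group = rep(c("wt", "mut"), each = 3))
    all(tidy(compare_bulk_survival(df))$p_adj < 0.01)
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # familywise error under the null
  fwe <- mean(vapply(1:200, function(s) {
    set.seed(1600 + s)
    df <- tibble::tibble(rate = 0.1 * exp(rnorm(9, 0, 0.3)),
                         group = rep(c("A", "B", "C"), each = 3))
    any(tidy(compare_bulk_survival(df))$p_adj < 0.05)
  }, logical(1)))
  expect_lte(fwe, 0.07)
  expect_error(compare_bulk_survival(
    tibble::tibble(rate = c(0.1, 0.2, 0.3), group = c("A", "A", "B"))),
    "< 2 replicates")
})

test_that("nested mixed-model LRT is calibrated and powered", {
  sim_nested <- function(seed, effect, n_bio = 8, n_tech = 2, n_obs = 2) {
    set.seed(seed)
    per <- n_bio * n_tech * n_obs
    g <- rep(c("A", "B"), each = per)
    bio <- rep(rep(seq_len(n_bio), each = n_tech * n_obs), 2)
    tech <- rep(rep(seq_len(n_tech), each = n_obs), 2 * n_bio)
    bio_id <- paste(g, bio)
    tech_id <- paste(bio_id, tech)
    bio_eff <- setNames(rnorm(length(unique(bio_id)), 0, 0.05),
                        unique(bio_id))
    tech_eff <- setNames(rnorm(length(unique(tech_id)), 0, 0.03),
                         unique(tech_id))
    tibble::tibble(
      y = ifelse(g == "B", effect, 0) + bio_eff[bio_id] + tech_eff[tech_id] +
        rnorm(2 * per, 0, 0.05),
      group = g, bio_rep = bio_id, tech_rep = tech)
  }
  # null: p-values roughly uniform
  ps <- vapply(1:200, function(s) {
    nested_mixed_lrt(sim_nested(s, 0), y, group, bio_rep, tech_rep)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # strong effect: decisive
  p_big <- nested_mixed_lrt(sim_nested(1, 1), y, group, bio_rep, tech_rep)
  expect_lt(p_big$p_value, 0.001)
  # single technical replicate: dropped with a warning
  one_tech <- sim_nested(2, 0)
  one_tech$tech_rep <- 1
  expect_warning(nested_mixed_lrt(one_tech, y, group, bio_rep, tech_rep),
                 "technical component dropped")
})

test_that("rank_compare shares the Wilcoxon implementation", {
  set.seed(135)
  a <- rnorm(50); b <- rnorm(50, 1)
  expect_identical(rank_compare(a, b), compare_relative_abundance(a, b))
})
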