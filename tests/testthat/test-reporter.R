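test_that("two-stage background correction matches hand arithmetic", {
  df <- tibble::tibble(raw = c(10, 12), bg = c(3, 3))
  out <- correct_intensities(df, raw, bg)
  expect_equal(out$corrected_intensity, c(0, 2))
  expect_equal(attr(out, "experiment_min"), 7)

  # the minimal colony is anchored at zero
  df2 <- tibble::tibble(raw = c(5, 9, 20), bg = c(5, 2, 4))
  out2 <- correct_intensities(df2, raw, bg)
  expect_equal(min(out2$corrected_intensity), 0)
  expect_true(all(out2$corrected_intensity >= 0))

  # shift invariance: adding a constant to all raw values changes nothing
  df3 <- df2
  df3$raw <- df3$raw + 11.3
  out3 <- correct_intensities(df3, raw, bg)
  expect_equal(out3$corrected_intensity, out2$corrected_intensity,
               tolerance = 1e-12)

  # idempotence on already-corrected values with zero background
  df4 <- tibble::tibble(raw = out2$corrected_intensity, bg = 0)
  out4 <- correct_intensities(df4, raw, bg)
  expect_equal(out4$corrected_intensity, df4$raw, tolerance = 1e-12)
})

test_that("spline smoother recovers exact linear relationships", {
  set.seed(111)
  df <- tibble::tibble(rate = runif(200, 0.1, 0.6))
  df$intensity <- 0.08 - 0.1 * df$rate
  sm <- intensity_growth_smoother(df, rate, intensity)
  expected <- 0.08 - 0.1 * sm$curve$rate
  expect_equal(sm$curve$fit, expected, tolerance = 1e-6)

  # flat coupling: CI band contains a horizontal line
  df$intensity <- 0.05 + rnorm(200, 0, 0.01)
  sm2 <- intensity_growth_smoother(df, rate, intensity)
  expect_true(any(sm2$curve$conf_lo <= mean(df$intensity)) &&
              any(sm2$curve$conf_hi >= mean(df$intensity)))
  expect_true(all(sm2$curve$conf_lo <= sm2$curve$fit))
  expect_error(intensity_growth_smoother(df[1:20, ], rate, intensity),
               "n >= 50")
})

test_that("default simulation yields a decreasing expression-growth curve", {
  cfg <- sim_config(n_colonies = 2000, seed = 112)
  pop <- simulate_population(cfg)
  pop$rate <- pop$true_rate
  np <- pop[!pop$is_petite, ]
  sm <- intensity_growth_smoother(np, rate, reporter_intensity)
  mid <- sm$curve[sm$curve$rate >= quantile(np$rate, 0.1) &
                  sm$curve$rate <= quantile(np$rate, 0.9), ]
  expect_true(all(diff(mid$fit) < 1e-6))
})

test_that("PAM recovers well-separated clusters and the k = 1 medoid", {
  set.seed(113)
  blob1 <- cbind(rnorm(150, 0, 0.3), rnorm(150, 0, 0.3))
  blob2 <- cbind(rnorm(150, 5, 0.3), rnorm(150, 5, 0.3))
  df <- tibble::tibble(x = c(blob1[, 1], blob2[, 1]),
                       y = c(blob1[, 2], blob2[, 2]),
                       label = rep(1:2, each = 150))
  res <- pam_cluster(df, x, y, k = 2)
  agreement <- max(mean(res$assignments$cluster == df$label),
                   mean(res$assignments$cluster == 3 - df$label))
  expect_gte(agreement, 0.99)
  expect_equal(sum(res$fractions), 1)

  # k = 1 medoid equals brute-force minimiser of summed distance
  sub <- df[sample.int(300, 80), ]
  res1 <- pam_cluster(sub, x, y, k = 1, standardize = FALSE)
  idx <- oracle_medoid1(cbind(sub$x, sub$y))
  expect_equal(unlist(res1$medoids[, c("x", "y")]),
               c(x = sub$x[idx], y = sub$y[idx]))

  # duplicating the dataset leaves the medoids (in original units) unchanged
  dup <- dplyr::bind_rows(df, df)
  res_dup <- pam_cluster(dup, x, y, k = 2)
  expect_setequal(round(res_dup$medoids$x, 9), round(res$medoids$x, 9))
  expect_error(pam_cluster(df[1:2, ], x, y, k = 2), "more points")
})

test_that("slower cluster sits at higher reporter intensity", {
  cfg <- sim_config(n_colonies = 1500, seed = 114)
  pop <- simulate_population(cfg)
  pop$rate <- pop$true_rate
  np <- pop[!pop$is_petite, ]
  res <- pam_cluster(np, rate, reporter_intensity, k = 2)
  m <- res$medoids[order(res$medoids$x), ]
  expect_lt(m$x[1], m$x[2])   # slower medoid...
  expect_gt(m$y[1], m$y[2])   # ...has strictly higher intensity
})

test_that("quantile-quantile regression detects shifts and scalings", {
  set.seed(115)
  control <- rlnorm(2000, 0, 0.4)
  res <- qq_compare(control + 5, control)
  expect_equal(res$slope, 1, tolerance = 1e-6)
  expect_equal(res$intercept, 5, tolerance = 1e-6)

  res2 <- qq_compare(2 * control, control)
  expect_equal(res2$slope, 2, tolerance = 1e-6)
  expect_equal(res2$intercept, 0, tolerance = 1e-6)

  # replacing the top 5% with huge values leaves the low window untouched
  poisoned <- sort(control)
  poisoned[1901:2000] <- poisoned[1901:2000] * 50
  res3 <- qq_compare(poisoned, control)
  expect_equal(res3$slope, 1, tolerance = 1e-6)
  expect_error(qq_compare(control, rep(1, 200)), "degenerate")
})

test_that("top-intensity gates select the right ranks", {
  set.seed(116)
  x <- rnorm(10000)
  g <- gate_bins(x, list(c(0, 0.2)))
  expect_length(g[[1]], 20)
  expect_gte(min(x[g[[1]]]), max(x[-g[[1]]]))

  all_idx <- gate_bins(x, list(c(0, 100)))[[1]]
  expect_setequal(all_idx, seq_along(x))

  # bin sizes match expected counts within 1 for any n
  for (n in c(37, 100, 999, 5000)) {
    xx <- rnorm(n)
    bins <- gate_bins(xx, "0-2, 5-7, 10-12, 20-25")
    expected <- c(0.02, 0.02, 0.02, 0.05) * n
    expect_true(all(abs(lengths(bins) - expected) <= 1))
  }
  expect_error(gate_bins(x, list(c(0, 5), c(4, 8))), "overlap")
  expect_error(gate_bins(x, list(c(5, 2))), "lo < hi")
})

test_that("cells gated on bright reporter grow slower than the population", {
  slower <- vapply(1:20, function(s) {
    cfg <- sim_config(n_colonies = 400, seed = s)
    pop <- simulate_population(cfg)
    bright <- gate_bins(pop$reporter_intensity, list(c(0, 5)))[[1]]
    median(pop$true_rate[bright]) < median(pop$true_rate)
  }, logical(1))
  expect_gte(mean(slower), 0.95)
})
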