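test_that("threshold below all intensities reproduces the full-sample medcouple", {
  set.seed(71)
  df <- tibble::tibble(mito_intensity = runif(500, 1, 2),
                       rate = rexp(500))
  scan <- threshold_scan(df, grid = c(0.5, 0.9), min_n = 10)
  expect_equal(scan$mc[1], medcouple_value(df$rate))
  expect_equal(scan$n_retained[1], 500)
})

test_that("sparse grid points are masked, not errors", {
  set.seed(72)
  df <- tibble::tibble(mito_intensity = runif(200), rate = rnorm(200))
  scan <- threshold_scan(df, grid = c(0, 0.5, 0.99, 2), min_n = 100)
  expect_true(is.na(scan$mc[3]))  # few retained
  expect_true(is.na(scan$mc[4]))  # none retained
  expect_false(is.na(scan$mc[1]))
  expect_error(threshold_scan(df, grid = c(1, 0.5)), "ascending")
})

test_that("single-class data with no coupling give a flat curve", {
  set.seed(73)
  df <- tibble::tibble(mito_intensity = rlnorm(3000, 0, 0.3),
                       rate = rnorm(3000, 0.4, 0.05))
  scan <- loess_smooth(threshold_scan(df, n_grid = 80, min_n = 100))
  plat <- detect_plateau(scan)
  # a large share of the evaluable grid is one flat run (limited only by
  # sampling noise in the per-threshold medcouples)
  expect_gt(length(plat$idx), sum(!is.na(scan$mc_smooth)) / 3)
  expect_lt(max(scan$mc_smooth[plat$idx]) - min(scan$mc_smooth[plat$idx]),
            0.1)
})

test_that("loess smoothing is exact on constant and linear input", {
  grid <- seq(0, 1, length.out = 50)
  scan_c <- structure(
    tibble::tibble(threshold = grid, n_retained = 500, mc = 0.3),
    class = c("threshold_scan", class(tibble::tibble())))
  sm <- loess_smooth(scan_c)
  expect_equal(sm$mc_smooth, rep(0.3, 50), tolerance = 1e-9)

  scan_l <- structure(
    tibble::tibble(threshold = grid, n_retained = 500, mc = 2 * grid - 0.5),
    class = c("threshold_scan", class(tibble::tibble())))
  sm_l <- loess_smooth(scan_l)
  expect_equal(sm_l$mc_smooth, 2 * grid - 0.5, tolerance = 1e-6)
  expect_error(loess_smooth(scan_l[1:5, ]), ">= 10")
})

test_that("loess tracks a smooth signal against a dense refit oracle", {
  set.seed(74)
  grid <- seq(0, 1, length.out = 120)
  truth <- sin(2 * pi * grid)
  noisy <- truth + rnorm(120, 0, 0.05)
  scan <- structure(
    tibble::tibble(threshold = grid, n_retained = 500, mc = noisy),
    class = c("threshold_scan", class(tibble::tibble())))
  sm <- loess_smooth(scan, span = 0.3)
  # oracle: independent loess at 10x grid density, same span
  dense <- stats::loess(mc ~ threshold, data = scan, span = 0.3, degree = 2,
                        control = stats::loess.control(surface = "direct"))
  oracle <- stats::predict(dense, newdata = grid)
  expect_equal(sm$mc_smooth, as.numeric(oracle), tolerance = 1e-8)
  expect_lt(mean(abs(sm$mc_smooth - truth)), 0.05)
})

test_that("plateau detection finds an exactly flat middle segment", {
  grid <- seq(0, 1, length.out = 60)
  y <- c(seq(0, 1, length.out = 20), rep(1, 20), seq(1, 2, length.out = 20))
  scan <- structure(
    tibble::tibble(threshold = grid, n_retained = 500, mc = y,
                   mc_smooth = y),
    class = c("threshold_scan", class(tibble::tibble())))
  plat <- detect_plateau(scan)
  expect_gte(plat$lo, grid[19])
  expect_lte(plat$hi, grid[42])
  expect_gt(plat$hi - plat$lo, 0.25)
})

test_that("a strictly monotone constant-slope curve has no plateau", {
  grid <- seq(0, 1, length.out = 40)
  scan <- structure(
    tibble::tibble(threshold = grid, n_retained = 500, mc = 2 * grid,
                   mc_smooth = 2 * grid),
    class = c("threshold_scan", class(tibble::tibble())))
  expect_error(detect_plateau(scan), "no plateau")
})

test_that("threshold selection takes the plateau midpoint", {
  expect_equal(select_threshold(c(0.01360, 0.01695)), 0.015275)
  expect_equal(select_threshold(c(0.4, 0.4)), 0.4)
  expect_equal(select_threshold(c(0, 1)), 0.5)
  expect_error(select_threshold(c(1, 0)), "lo <= hi")
})

test_that("common threshold is the mean of per-strain thresholds", {
  expect_equal(common_threshold(0.021), 0.021)
  expect_equal(common_threshold(c(0.01, 0.02)), 0.015)
  expect_equal(common_threshold(rep(0.017, 5)), 0.017)
  expect_error(common_threshold(numeric(0)), "at least one")
})

test_that("apply_threshold keeps boundary colonies and reports exclusions", {
  df <- tibble::tibble(mito_intensity = c(1, 2, 3, 4, 5), rate = 1:5)
  none <- apply_threshold(df, 0.5)
  expect_equal(nrow(none), 5)
  expect_equal(exclusion_report(none)$n_excluded, 0)

  at <- apply_threshold(df, 3)
  expect_equal(nrow(at), 3)          # >= retains the colony exactly at 3
  expect_true(3 %in% at$mito_intensity)

  # scale sweep moves only boundary colonies
  lo <- apply_threshold(df, 3, scale = 0.9)
  hi <- apply_threshold(df, 3, scale = 1.1)
  expect_equal(setdiff(lo$rate, at$rate), numeric(0))
  expect_true(all(hi$rate %in% at$rate))
})

test_that("default synthetic mixture yields a plateau between the intensity modes", {
  cfg <- sim_config(n_colonies = 3000, seed = 83)
  pop <- simulate_population(cfg)
  pop$rate <- pop$true_rate
  sel <- select_mito_threshold(pop, n_grid = 150)
  pet_mode <- exp(cfg$mito_params$petite_meanlog)
  np_mode <- exp(cfg$mito_params$meanlog)
  expect_gt(sel$plateau$lo, pet_mode)
  expect_lt(sel$plateau$hi, np_mode)
  # threshold excludes nearly all petites, hardly any non-petites
  expect_gte(mean(pop$mito_intensity[pop$is_petite] < sel$threshold), 0.9)
  expect_lte(mean(pop$mito_intensity[!pop$is_petite] < sel$threshold), 0.05)
})
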