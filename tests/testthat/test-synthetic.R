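test_that("identical config and seed reproduce identical outputs", {
  cfg <- small_cfg(n = 300, seed = 9)
  expect_identical(simulate_population(cfg), simulate_population(cfg))
  expect_identical(simulate_msn2_cells(cfg, 40), simulate_msn2_cells(cfg, 40))
  pop <- simulate_population(cfg)
  expect_identical(simulate_heatshock(pop, cfg), simulate_heatshock(pop, cfg))
})

test_that("noise-free limit produces exact lagged exponentials", {
  cfg <- small_cfg(n = 60, seed = 14, petite_frac = 0, slow_tail_weight = 0,
                   area_noise = 0)
  pop <- simulate_population(cfg)
  for (i in seq_len(10)) {
    a <- as.numeric(pop[i, sprintf("area_h%d", 0:10)])
    expected <- a[1] * exp(pop$true_rate[i] * pmax(0, 0:10 - pop$lag[i]))
    expect_equal(a, expected, tolerance = 1e-12)
  }
})

test_that("petite assignment frequency matches the configured fraction", {
  cfg <- sim_config(n_colonies = 10000, petite_frac = 0.16, seed = 31)
  pop <- simulate_population(cfg)
  k <- sum(pop$is_petite)
  # binomial 99% CI around 0.16 at n = 10000
  ci <- qbinom(c(0.005, 0.995), 10000, 0.16)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("slow tail induces a negative medcouple in non-petite rates", {
  for (s in c(3, 19)) {
    cfg <- sim_config(n_colonies = 2500, seed = s)
    pop <- simulate_population(cfg)
    expect_lt(medcouple_value(pop$true_rate[!pop$is_petite]), 0)
  }
  # no tail: no forced left skew
  cfg0 <- sim_config(n_colonies = 2500, seed = 3, slow_tail_weight = 0)
  pop0 <- simulate_population(cfg0)
  expect_gt(medcouple_value(pop0$true_rate[!pop0$is_petite]), -0.05)
})

test_that("configuration errors are caught", {
  expect_error(sim_config(petite_frac = 1.2), "proportion")
  expect_error(sim_config(fast_mode_rate = -1), "positive")
  expect_error(sim_config(n_colonies = 0), ">= 1")
  expect_error(sim_config(times = c(0, 2, 1)), "increasing")
})

test_that("Msn2 generator honours its degenerate limits", {
  # zero amplitude and zero noise: constant ratio, zero occupancy
  cfg <- small_cfg(seed = 8, msn2_params = list(pulse_amplitude = 0,
                                                ratio_noise = 0))
  cells <- simulate_msn2_cells(cfg, 30)
  occ <- compute_occupancy(cells$cells, correct_bg = TRUE)
  expect_equal(occ$occupancy, rep(0, 30), tolerance = 1e-12)

  # zero truncation: every series has the full 30 points
  cfg2 <- small_cfg(seed = 8, msn2_params = list(truncation_prob = 0))
  cells2 <- simulate_msn2_cells(cfg2, 30)
  expect_true(all(table(cells2$cells$cell_id) == 30))
})

test_that("occupancy-growth coupling is recoverable from simulated cells", {
  signs <- vapply(1:6, function(s) {
    cfg <- small_cfg(seed = s)
    cells <- simulate_msn2_cells(cfg, 250)
    occ <- compute_occupancy(cells$cells, correct_bg = TRUE)
    occ$rate <- cells$latent$true_rate[match(occ$cell_id,
                                             cells$latent$cell_id)]
    fit <- occupancy_growth_regression(occ[!is.na(occ$occupancy), ])
    glance(fit)$slope < 0
  }, logical(1))
  expect_true(all(signs))
})

test_that("heat-shock generator honours its degenerate limits", {
  cfg <- small_cfg(n = 80, seed = 44,
                   survival_logit = c(intercept = 50, slope = 0),
                   global_shift = c(0, 0), centroid_jitter = 0)
  pop <- simulate_population(cfg)
  hs <- simulate_heatshock(pop, cfg)
  expect_true(all(hs$latent$alive))
  # survivors at least double
  post_max <- apply(as.matrix(hs$post[, sprintf("area_h%d", 0:15)]), 1, max)
  pre_final <- hs$pre$area_h5[match(hs$latent$pre_id, hs$pre$colony_id)]
  post_ord <- post_max[match(hs$latent$post_id, hs$post$colony_id)]
  expect_true(all(post_ord >= 2 * pre_final))
  # no shift, no jitter: centroids coincide
  pre_xy <- hs$pre[match(hs$latent$pre_id, hs$pre$colony_id),
                   c("centroid_x", "centroid_y")]
  post_xy <- hs$post[match(hs$latent$post_id, hs$post$colony_id),
                     c("centroid_x", "centroid_y")]
  expect_equal(as.matrix(pre_xy), as.matrix(post_xy),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("steep survival logit yields survival decreasing across terciles", {
  cfg <- sim_config(n_colonies = 3000, seed = 55)
  pop <- simulate_population(cfg)
  hs <- simulate_heatshock(pop, cfg)
  terciles <- cut(hs$latent$true_rate,
                  quantile(hs$latent$true_rate, c(0, 1/3, 2/3, 1)),
                  include.lowest = TRUE, labels = FALSE)
  rates <- tapply(hs$latent$alive, terciles, mean)
  expect_true(rates[1] > rates[2] && rates[2] > rates[3])
})

test_that("CSV round-trip is lossless and validates its schema", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(n = 50, seed = 61)
  pop <- simulate_population(cfg)
  stem <- file.path(dir, "pop")
  write_tables(pop, stem)
  back <- read_tables(stem, "population")
  expect_equal(as.data.frame(back), as.data.frame(pop)[, names(back)],
               tolerance = 1e-12)
  # latent columns live only in the sidecar
  obs <- readr::read_csv(paste0(stem, ".csv"), show_col_types = FALSE)
  expect_false(any(c("true_rate", "is_petite") %in% names(obs)))

  # missing required column: error naming it
  broken <- obs[, setdiff(names(obs), "mito_intensity")]
  stem2 <- file.path(dir, "broken")
  readr::write_csv(broken, paste0(stem2, ".csv"))
  expect_error(read_tables(stem2, "population"), "mito_intensity")

  # extra unknown columns preserved untouched
  extra <- obs
  extra$operator_note <- paste0("n", seq_len(nrow(extra)))
  stem3 <- file.path(dir, "extra")
  readr::write_csv(extra, paste0(stem3, ".csv"))
  back3 <- read_tables(stem3, "population")
  expect_identical(back3$operator_note, extra$operator_note)

  # msn2 and heat-shock phases round-trip too
  cells <- simulate_msn2_cells(cfg, 12)
  write_tables(cells, file.path(dir, "cells"))
  cback <- read_tables(file.path(dir, "cells"), "msn2")
  expect_equal(as.data.frame(cback$cells), as.data.frame(cells$cells),
               tolerance = 1e-12)
  hs <- simulate_heatshock(pop, cfg)
  write_tables(hs, file.path(dir, "hs"))
  hback <- read_tables(file.path(dir, "hs"), "heatshock")
  expect_equal(as.data.frame(hback$pre), as.data.frame(hs$pre),
               tolerance = 1e-12)
  expect_equal(hback$latent$alive, hs$latent$alive)
})
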