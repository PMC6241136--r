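#' Simulate a microcolony population
#'
#' Draws a seeded synthetic population with the heterogeneity structure the
#' downstream analyses assume. Non-petite growth rates are a mixture of a
#' Gaussian fast mode and an exponential tail below the mode (weight
#' `slow_tail_weight`), producing the left-skewed (negative-medcouple)
#' distribution characteristic of clonal populations carrying a slow-growing,
#' stress-protected sub-state. Petite rates are the fast mode shifted down by
#' `petite_rate_shift`. MitoTracker intensities are log-normal per class, with
#' a weak positive coupling to growth among non-petites and a minor bright
#' petite mode that creates partial overlap between the classes. Reporter
#' intensity is affine in rate (negative slope) plus noise, floored at zero.
#' Area series are lagged exponentials with multiplicative log-normal noise.
#'
#' Latent truth (`true_rate`, `lag`, `is_petite`) is carried in the returned
#' table but written to a separate sidecar file by [write_tables()], so
#' recovery tests cannot leak it through the observable CSV.
#'
#' @param config A [sim_config()].
#' @param label Strain/condition label recorded per colony.
#' @return A tibble of class `microhet_population`: one row per colony with
#'   identifiers (`colony_id`, `strain`, `plate`, `well`, `field`), centroids,
#'   `mito_intensity`, `reporter_intensity`, hourly area columns
#'   `area_h<t>`, and latent columns `true_rate`, `lag`, `is_petite`.
#' @examples
#' pop <- simulate_population(sim_config(n_colonies = 200, seed = 7))
#' dplyr::count(pop, is_petite)
#' @export
simulate_population <- function(config = sim_config(), label = "strainA") {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(config$seed, simulate_population_impl(config, label))
}

simulate_population_impl <- function(config, label) {
  n <- as.integer(config$n_colonies)
  is_petite <- runif(n) < config$petite_frac

  rate <- draw_rates(n, is_petite, config)

  # plate/well/field layout + optional random effects on rate
  plate <- sprintf("P%02d", 1 + (seq_len(n) - 1) %% config$n_plates)
  well <- sprintf("W%02d", 1 + ((seq_len(n) - 1) %/% config$n_plates) %% config$n_wells)
  field <- sprintf("F%02d",
    1 + ((seq_len(n) - 1) %/% (config$n_plates * config$n_wells)) %% config$n_fields)
  es <- config$effect_sds
  rate <- rate +
    random_effect(plate, es[["plate"]]) +
    random_effect(paste(plate, well), es[["well"]]) +
    random_effect(paste(plate, well, field), es[["field"]])
  rate <- pmax(rate, config$min_rate)

  mito <- draw_mito(rate, is_petite, config)
  rc <- config$reporter_coupling
  reporter <- pmax(0, rc$intercept + rc$slope * rate + rnorm(n, 0, rc$noise_sd))

  lag <- runif(n, config$lag_params$min, config$lag_params$max)
  a0 <- rlnorm(n, config$init_area$meanlog, config$init_area$sdlog)
  areas <- area_series(a0, rate, lag, config$times, config$area_noise)
  colnames(areas) <- sprintf("area_h%d", config$times)

  pop <- tibble(
    colony_id = sprintf("c%05d", seq_len(n)),
    strain = label, plate = plate, well = well, field = field,
    centroid_x = runif(n, 0, config$field_size),
    centroid_y = runif(n, 0, config$field_size),
    mito_intensity = mito,
    reporter_intensity = reporter,
    as_tibble(areas),
    true_rate = rate, lag = lag, is_petite = is_petite
  )
  class(pop) <- c("microhet_population", class(pop))
  pop
}

draw_rates <- function(n, is_petite, config) {
  rate <- numeric(n)
  np <- !is_petite
  n_np <- sum(np)
  if (n_np > 0) {
    slow <- runif(n_np) < config$slow_tail_weight
    r <- rnorm(n_np, config$fast_mode_rate, config$fast_mode_sd)
    r[slow] <- config$fast_mode_rate - rexp(sum(slow), 1 / config$slow_tail_scale)
    rate[np] <- r
  }
  n_p <- sum(is_petite)
  if (n_p > 0) {
    rate[is_petite] <- rnorm(n_p, config$fast_mode_rate - config$petite_rate_shift,
                             config$petite_rate_sd)
  }
  pmax(rate, config$min_rate)
}

draw_mito <- function(rate, is_petite, config) {
  mp <- config$mito_params
  n <- length(rate)
  mito <- numeric(n)
  np <- !is_petite
  if (any(np)) {
    # coupling saturates below coupling_floor_rate: dim-and-slow association
    # holds in the mid-rate range without dragging the slowest cells into the
    # petite intensity band
    eff_rate <- pmax(rate[np], mp$coupling_floor_rate)
    mu <- mp$meanlog + mp$coupling * (eff_rate - config$fast_mode_rate)
    mito[np] <- rlnorm(sum(np), mu, mp$sdlog)
  }
  if (any(is_petite)) {
    n_p <- sum(is_petite)
    minor <- runif(n_p) < mp$petite_minor_weight
    m <- rlnorm(n_p, mp$petite_meanlog, mp$petite_sdlog)
    m[minor] <- rlnorm(sum(minor), mp$petite_minor_meanlog, mp$petite_minor_sdlog)
    mito[is_petite] <- m
  }
  mito
}

random_effect <- function(labels, sd) {
  if (is.null(sd) || sd == 0) return(0)
  lv <- unique(labels)
  eff <- setNames(rnorm(length(lv), 0, sd), lv)
  eff[labels]
}

# Lagged exponential areas with multiplicative log-normal noise.
area_series <- function(a0, rate, lag, times, noise_sd) {
  n <- length(a0)
  out <- matrix(NA_real_, n, length(times))
  for (k in seq_along(times)) {
    mu <- a0 * exp(rate * pmax(0, times[k] - lag))
    out[, k] <- if (noise_sd > 0) mu * rlnorm(n, 0, noise_sd) else mu
  }
  out
}

#' Simulate single-cell Msn2 localisation time series
#'
#' Each cell receives up to 30 per-minute records of nucleus, cytoplasm and
#' bounding-box-background median intensities. The latent nuclear ratio series
#' is a baseline plus a train of exponential-profile pulses whose count and
#' amplitude scale with the cell's pulse propensity, itself negatively coupled
#' to the cell's latent growth rate: slow-growing cells pulse more and harder,
#' so their total nuclear occupancy is higher. A fraction of cells is
#' truncated to fewer than 30 points, mimicking tracking loss.
#'
#' Intensities are constructed so that the background-corrected ratio
#' `(nuc - bg) / (cyt - bg)` reproduces the latent ratio exactly.
#'
#' @param config A [sim_config()]; `msn2_params` controls this generator.
#' @param n_cells Number of cells.
#' @return A list of class `msn2_cells`: `$cells`, a long tibble
#'   (`cell_id`, `t_min`, `nuc_median`, `cyt_median`, `bbox_bg_median`), and
#'   `$latent` (`cell_id`, `true_rate`, `pulse_propensity`, `n_pulses`).
#' @export
simulate_msn2_cells <- function(config = sim_config(), n_cells = 200) {
  stopifnot(inherits(config, "sim_config"), n_cells >= 1)
  with_seed_if(config$seed, simulate_msn2_impl(config, as.integer(n_cells)))
}

simulate_msn2_impl <- function(config, n_cells) {
  mp <- config$msn2_params
  nt <- mp$n_times
  rate <- draw_rates(n_cells, rep(FALSE, n_cells), config)
  propensity <- pmax(0, 1 + mp$occupancy_growth_coupling *
                          (rate - config$fast_mode_rate))

  cells <- purrr::map(seq_len(n_cells), function(i) {
    len <- nt
    if (runif(1) < mp$truncation_prob) len <- sample(5:(nt - 1), 1)
    tt <- seq_len(len)
    n_pulses <- rpois(1, mp$pulse_rate * propensity[i])
    ratio <- rep(mp$baseline_ratio, len)
    if (n_pulses > 0 && mp$pulse_amplitude > 0) {
      centers <- runif(n_pulses, 1, nt)
      amps <- mp$pulse_amplitude * propensity[i] * runif(n_pulses, 0.5, 1.5)
      for (p in seq_len(n_pulses)) {
        ratio <- ratio + amps[p] * exp(-abs(tt - centers[p]) / mp$pulse_width)
      }
    }
    if (mp$ratio_noise > 0) ratio <- ratio + rnorm(len, 0, mp$ratio_noise)
    bg <- pmax(1, rnorm(len, mp$bg_level, mp$bg_sd))
    cyt <- pmax(bg + 1, rnorm(len, mp$cyt_level, mp$cyt_sd))
    tibble(
      cell_id = sprintf("cell%04d", i), t_min = tt,
      nuc_median = bg + ratio * (cyt - bg),
      cyt_median = cyt, bbox_bg_median = bg,
      n_pulses = n_pulses
    )
  })
  cells <- dplyr::bind_rows(cells)
  latent <- dplyr::distinct(cells, .data$cell_id, .data$n_pulses)
  latent$true_rate <- rate
  latent$pulse_propensity <- propensity
  cells$n_pulses <- NULL
  out <- list(cells = cells,
              latent = latent[, c("cell_id", "true_rate", "pulse_propensity",
                                  "n_pulses")])
  class(out) <- "msn2_cells"
  out
}

#' Simulate an acute heat-shock experiment on a population
#'
#' Splits each colony's trajectory into a 5 h pre-shock phase and a 15 h
#' post-shock phase. Survival is Bernoulli with logit linear in the latent
#' growth rate (`config$survival_logit`): slow growers, which carry
#' pre-existing stress protection, survive more often. Survivors resume
#' exponential growth from their final pre-shock area (at no less than
#' `recovery_min_rate`); dead colonies fluctuate within measurement noise of
#' their final pre-shock area. Post-phase centroids are the pre-phase
#' centroids displaced by the global stage shift plus jitter, and post-phase
#' colony identities are scrambled, so downstream lineage matching must be
#' earned. True pre/post identity and survival live in `$latent`.
#'
#' @param pop A population from [simulate_population()].
#' @param config The [sim_config()] used to generate it.
#' @param pre_hours Length of the pre-shock phase (h).
#' @param post_hours Length of the post-shock phase (h).
#' @return List of class `heatshock_phases`: `$pre` (colony_id, centroids,
#'   `area_h0..area_h<pre>`), `$post` (scrambled `colony_id`, centroids,
#'   `area_h0..area_h<post>` measured from the shock), `$latent`
#'   (`pre_id`, `post_id`, `alive`, `true_rate`).
#' @export
simulate_heatshock <- function(pop, config = sim_config(),
                               pre_hours = 5, post_hours = 15) {
  stopifnot(inherits(config, "sim_config"), nrow(pop) > 0)
  with_seed_if(derive_seeds(config$seed, 3)[[3]],
               simulate_heatshock_impl(pop, config, pre_hours, post_hours))
}

simulate_heatshock_impl <- function(pop, config, pre_hours, post_hours) {
  n <- nrow(pop)
  pre_times <- config$times[config$times <= pre_hours]
  pre_cols <- sprintf("area_h%d", pre_times)
  missing <- setdiff(pre_cols, names(pop))
  if (length(missing) > 0) {
    abort(sprintf("population lacks pre-shock area columns: %s",
                  paste(missing, collapse = ", ")))
  }
  pre <- dplyr::select(as_tibble(pop), "colony_id", "centroid_x", "centroid_y",
                       dplyr::all_of(pre_cols))

  p_surv <- plogis(config$survival_logit[[1]] +
                   config$survival_logit[[2]] * pop$true_rate)
  alive <- runif(n) < p_surv

  final_pre <- pop[[sprintf("area_h%d", max(pre_times))]]
  post_times <- 0:post_hours
  grow_rate <- pmax(pop$true_rate, config$recovery_min_rate)
  areas <- matrix(NA_real_, n, length(post_times))
  for (k in seq_along(post_times)) {
    mu <- ifelse(alive, final_pre * exp(grow_rate * post_times[k]), final_pre)
    sdl <- ifelse(alive, config$area_noise, config$dead_area_noise)
    areas[, k] <- mu * rlnorm(n, 0, sdl)
  }
  colnames(areas) <- sprintf("area_h%d", post_times)

  shuffle <- sample.int(n)
  post <- tibble(
    centroid_x = pop$centroid_x + config$global_shift[[1]] +
      rnorm(n, 0, config$centroid_jitter),
    centroid_y = pop$centroid_y + config$global_shift[[2]] +
      rnorm(n, 0, config$centroid_jitter),
    as_tibble(areas)
  )[shuffle, ]
  post <- dplyr::bind_cols(
    tibble(colony_id = sprintf("post%05d", seq_len(n))), post
  )

  latent <- tibble(
    pre_id = pop$colony_id,
    # original colony i sits at post row match(i, shuffle)
    post_id = post$colony_id[match(seq_len(n), shuffle)],
    alive = alive,
    true_rate = pop$true_rate
  )
  out <- list(pre = pre, post = post, latent = latent)
  class(out) <- "heatshock_phases"
  out
}
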