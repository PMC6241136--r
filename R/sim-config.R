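#' Configuration for the synthetic microcolony population generator
#'
#' Bundles every parameter of the generative model used by
#' [simulate_population()], [simulate_msn2_cells()] and [simulate_heatshock()].
#' Defaults describe a wild-type-like haploid yeast population on rich medium:
#' a fast growth mode near 0.43 h^-1 with a heavy left tail of slow growers, a
#' 16% petite (respiration-deficient) sub-population with low MitoTracker
#' intensity and strongly reduced growth, a weak positive MitoTracker-growth
#' coupling among non-petites, stress-reporter expression negatively coupled
#' to growth, pulsatile Msn2 nuclear localisation whose occupancy rises as
#' growth falls, and acute-heat-shock survival declining with growth rate.
#'
#' @param n_colonies Number of microcolonies to simulate.
#' @param petite_frac Proportion of petite colonies.
#' @param fast_mode_rate Centre of the fast growth mode (h^-1).
#' @param fast_mode_sd SD of the Gaussian fast mode (h^-1).
#' @param slow_tail_weight Proportion of non-petites drawn from the slow tail.
#' @param slow_tail_scale Mean of the exponential drop below the mode (h^-1);
#'   slow-tail rates are `fast_mode_rate - Exp(slow_tail_scale)`.
#' @param petite_rate_shift Downward shift of the petite growth mode (h^-1).
#' @param petite_rate_sd SD of the petite growth mode (h^-1).
#' @param min_rate Floor applied to all simulated rates (h^-1).
#' @param mito_params Per-class MitoTracker intensity model (log-normal
#'   parameters, a.u.): non-petite `meanlog`/`sdlog` plus `coupling`, the
#'   log-intensity slope on (rate - fast mode); petite main mode
#'   `petite_meanlog`/`petite_sdlog` (the default heavy log-scale spread
#'   produces a continuum of bright petites partially overlapping the
#'   non-petite class), plus an optional discrete brighter mode
#'   (`petite_minor_weight`, off by default, `petite_minor_meanlog`,
#'   `petite_minor_sdlog`).
#' @param reporter_coupling Reporter (e.g. Tsl1-GFP) model: `intercept` and
#'   (negative) `slope` of mean intensity on growth rate, plus Gaussian
#'   `noise_sd`; intensities are floored at 0.
#' @param msn2_params Msn2 localisation model: `pulse_rate` (expected pulses
#'   per 30 min at the fast mode), `pulse_amplitude` (ratio units),
#'   `baseline_ratio`, `occupancy_growth_coupling` (slope of the latent
#'   pulse-propensity multiplier on rate; negative), `ratio_noise`,
#'   `pulse_width` (min), `truncation_prob` (chance a cell's track is cut
#'   short), `cyt_level`, `cyt_sd`, `bg_level`, `bg_sd` (a.u.).
#' @param survival_logit Length-2 vector `c(intercept, slope)` of the survival
#'   logit on the true growth rate (h^-1).
#' @param area_noise SD of multiplicative log-normal area measurement noise.
#' @param lag_params Uniform lag-duration bounds `list(min, max)` in hours.
#' @param init_area Log-normal parameters of the initial colony area
#'   (pixel^2 analogue).
#' @param global_shift Length-2 vector: post-heat-shock coordinate
#'   displacement (px).
#' @param centroid_jitter SD of per-colony centroid jitter after the shift (px).
#' @param dead_area_noise SD of log-area fluctuation of dead colonies.
#' @param recovery_min_rate Minimum post-shock regrowth rate of survivors
#'   (h^-1); slow survivors resume growth at least this fast.
#' @param field_size Side length of the imaged arena (px); centroids are
#'   uniform on the square.
#' @param effect_sds Named vector `c(plate=, well=, field=)` of SDs of
#'   Gaussian random effects added to the growth rate (default all 0).
#' @param n_plates,n_wells,n_fields Plate/well/field layout labels.
#' @param times Hourly imaging time points (h).
#' @param seed Integer RNG seed; identical (config, seed) pairs reproduce
#'   identical outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_colonies = 4000,
                       petite_frac = 0.16,
                       fast_mode_rate = 0.43,
                       fast_mode_sd = 0.045,
                       slow_tail_weight = 0.25,
                       slow_tail_scale = 0.15,
                       petite_rate_shift = 0.25,
                       petite_rate_sd = 0.04,
                       min_rate = 0.02,
                       mito_params = list(),
                       reporter_coupling = list(),
                       msn2_params = list(),
                       survival_logit = c(intercept = 4, slope = -10),
                       area_noise = 0.05,
                       lag_params = list(min = 0, max = 2),
                       init_area = list(meanlog = log(150), sdlog = 0.2),
                       global_shift = c(35, -18),
                       centroid_jitter = 1,
                       dead_area_noise = 0.02,
                       recovery_min_rate = 0.1,
                       field_size = 2000,
                       effect_sds = c(plate = 0, well = 0, field = 0),
                       n_plates = 2, n_wells = 4, n_fields = 4,
                       times = 0:10,
                       seed = 1L) {
  mito <- modifyList(list(
    meanlog = log(0.035), sdlog = 0.18, coupling = 2, coupling_floor_rate = 0.3,
    petite_meanlog = log(0.005), petite_sdlog = 0.5,
    petite_minor_weight = 0, petite_minor_meanlog = log(0.02),
    petite_minor_sdlog = 0.25
  ), mito_params)
  rep_cfg <- modifyList(list(
    intercept = 0.05, slope = -0.08, noise_sd = 0.008
  ), reporter_coupling)
  msn2 <- modifyList(list(
    pulse_rate = 3, pulse_amplitude = 0.6, baseline_ratio = 1,
    occupancy_growth_coupling = -8, ratio_noise = 0.02, pulse_width = 1.5,
    truncation_prob = 0.2, cyt_level = 100, cyt_sd = 5,
    bg_level = 20, bg_sd = 2, n_times = 30L
  ), msn2_params)

  cfg <- list(
    n_colonies = n_colonies, petite_frac = petite_frac,
    fast_mode_rate = fast_mode_rate, fast_mode_sd = fast_mode_sd,
    slow_tail_weight = slow_tail_weight, slow_tail_scale = slow_tail_scale,
    petite_rate_shift = petite_rate_shift, petite_rate_sd = petite_rate_sd,
    min_rate = min_rate, mito_params = mito, reporter_coupling = rep_cfg,
    msn2_params = msn2, survival_logit = survival_logit,
    area_noise = area_noise, lag_params = lag_params, init_area = init_area,
    global_shift = global_shift, centroid_jitter = centroid_jitter,
    dead_area_noise = dead_area_noise, recovery_min_rate = recovery_min_rate,
    field_size = field_size, effect_sds = effect_sds,
    n_plates = n_plates, n_wells = n_wells, n_fields = n_fields,
    times = times, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_colonies) || cfg$n_colonies < 1) {
    abort("`n_colonies` must be >= 1")
  }
  check_proportion(cfg$petite_frac, "petite_frac")
  check_proportion(cfg$slow_tail_weight, "slow_tail_weight")
  check_proportion(cfg$msn2_params$truncation_prob, "msn2_params$truncation_prob")
  check_positive(cfg$fast_mode_rate, "fast_mode_rate")
  check_positive(cfg$slow_tail_scale, "slow_tail_scale")
  check_nonneg(cfg$petite_rate_shift, "petite_rate_shift")
  check_nonneg(cfg$area_noise, "area_noise")
  check_nonneg(cfg$centroid_jitter, "centroid_jitter")
  if (length(cfg$survival_logit) != 2) {
    abort("`survival_logit` must be c(intercept, slope)")
  }
  if (length(cfg$global_shift) != 2) {
    abort("`global_shift` must be a 2-vector")
  }
  if (is.unsorted(cfg$times, strictly = TRUE)) {
    abort("`times` must be strictly increasing")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d colonies, petite fraction %.3f, seed %d\n",
              x$n_colonies, x$petite_frac, x$seed))
  cat(sprintf("  fast mode %.3f h^-1 (sd %.3f), slow-tail weight %.2f (scale %.2f)\n",
              x$fast_mode_rate, x$fast_mode_sd, x$slow_tail_weight,
              x$slow_tail_scale))
  cat(sprintf("  petite rate shift -%.2f h^-1; survival logit (%g, %g)\n",
              x$petite_rate_shift, x$survival_logit[1], x$survival_logit[2]))
  invisible(x)
}
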