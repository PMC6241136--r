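#' Configuration for a full analysis run
#'
#' @param sim A [sim_config()] describing the population to simulate (the
#'   demo mode; supply `pop` to [run_pipeline()] to analyse existing data).
#' @param seed Root seed; every stochastic stage receives a sub-seed derived
#'   deterministically from it, so reruns are byte-identical.
#' @param threshold_mode `"per-strain"`, `"common"` (mean of per-strain
#'   thresholds) or `"fixed"`.
#' @param fixed_threshold Threshold used when `threshold_mode = "fixed"`.
#' @param threshold_scale Multiplier for the robustness sweep (0.9, 1.0 or
#'   1.1).
#' @param min_points,min_r2 Growth-fit parameters.
#' @param span,flat_frac,n_grid,min_n Threshold-scan parameters.
#' @param n_msn2_cells Cells for the Msn2 stage (0 skips it).
#' @param run_heatshock Include the heat-shock survival stage.
#' @param out_dir Optional directory; when set, stage tables are written as
#'   CSV.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), seed = 1,
                       threshold_mode = c("per-strain", "common", "fixed"),
                       fixed_threshold = NULL, threshold_scale = 1,
                       min_points = 4, min_r2 = 0.9, span = 0.4,
                       flat_frac = 0.25, n_grid = 200, min_n = 100,
                       n_msn2_cells = 200, run_heatshock = TRUE,
                       out_dir = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed" && is.null(fixed_threshold)) {
    abort("fixed threshold mode requires `fixed_threshold`")
  }
  structure(list(
    sim = sim, seed = as.integer(seed), threshold_mode = threshold_mode,
    fixed_threshold = fixed_threshold, threshold_scale = threshold_scale,
    min_points = min_points, min_r2 = min_r2, span = span,
    flat_frac = flat_frac, n_grid = n_grid, min_n = min_n,
    n_msn2_cells = n_msn2_cells, run_heatshock = run_heatshock,
    out_dir = out_dir
  ), class = "run_config")
}

#' Run the full microcolony analysis pipeline
#'
#' Simulate (or accept) a population, fit growth rates, select the
#' MitoTracker threshold by medcouple scan, filter petites, estimate residual
#' contamination, smooth reporter expression against growth, compute Msn2
#' occupancies and their growth regression, and run the lineage-matched
#' heat-shock survival analysis. Every stage logs its key numbers; the whole
#' run is reproducible from (config, seed).
#'
#' @param config A [run_config()].
#' @param pop Optional existing population table (otherwise simulated from
#'   `config$sim` with a seed derived from the root seed).
#' @return A list of class `microhet_run` with stage results (`pop`, `fits`,
#'   `scan`, `plateau`, `threshold`, `filtered`, `exclusion`,
#'   `contamination`, `growth_cdf`, `reporter_curve`, `occupancy`,
#'   `occupancy_fit`, `survival`, `log`).
#' @export
run_pipeline <- function(config = run_config(), pop = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 6)
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    rlang::inform(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }

  if (is.null(pop)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- seeds[[1]][[1]]
    pop <- stage("simulate", simulate_population(sim_cfg))
    say("simulated %d colonies (seed %d)", nrow(pop), sim_cfg$seed)
  }

  fits <- stage("growth_fit",
                fit_population(pop, config$min_points, config$min_r2,
                               quiet = TRUE))
  say("growth fits: %s",
      paste(sprintf("%s=%d", names(table(fits$flag)), table(fits$flag)),
            collapse = ", "))
  usable <- fits[fits$flag == "ok", ]

  # threshold selection per strain, then combined per threshold_mode
  thr <- stage("threshold", {
    if (config$threshold_mode == "fixed") {
      list(threshold = config$fixed_threshold, scan = NULL, plateau = NULL)
    } else {
      per_strain <- lapply(split(usable, usable$strain), function(d) {
        select_mito_threshold(d, n_grid = config$n_grid, min_n = config$min_n,
                              span = config$span, flat_frac = config$flat_frac)
      })
      ts <- vapply(per_strain, `[[`, numeric(1), "threshold")
      t_use <- if (config$threshold_mode == "common") common_threshold(ts) else ts[[1]]
      list(threshold = t_use, scan = per_strain[[1]]$scan,
           plateau = per_strain[[1]]$plateau, per_strain = ts)
    }
  })
  say("selected threshold %.6g (mode %s, scale %.2f)", thr$threshold,
      config$threshold_mode, config$threshold_scale)

  filtered <- apply_threshold(usable, thr$threshold,
                              scale = config$threshold_scale)
  excl <- exclusion_report(filtered)
  say("threshold filter: retained %d / %d (excluded %.2f%%)",
      excl$n_retained, excl$n_total, 100 * excl$frac_excluded)

  b <- excl$frac_excluded
  contamination <- if (b > 0 && b < 1) {
    # reference overlap proxy: latent petites above threshold if available
    a_ref <- if ("is_petite" %in% names(usable) && any(usable$is_petite)) {
      mean(usable$mito_intensity[usable$is_petite] >=
             config$threshold_scale * thr$threshold)
    } else NA_real_
    if (is.finite(a_ref) && a_ref < 1) petite_contamination(b, a_ref) else NULL
  } else NULL
  if (!is.null(contamination)) {
    say("petite estimates: total %.4g%%, contamination %.4g%%",
        100 * contamination$p_total, 100 * contamination$contamination)
  }

  # growth-rate cumulative density data before/after filtering; the
  # square-root density-axis convention is recorded in plot metadata
  growth_cdf <- dplyr::bind_rows(
    tibble(set = "before", rate = sort(usable$rate),
           cdf = seq_along(usable$rate) / nrow(usable)),
    tibble(set = "after", rate = sort(filtered$rate),
           cdf = seq_len(nrow(filtered)) / nrow(filtered))
  )
  attr(growth_cdf, "axis_note") <- "plot density/CDF axis on square-root scale"

  reporter_curve <- stage("reporter",
    intensity_growth_smoother(filtered, rate, reporter_intensity))

  occupancy <- occupancy_fit <- NULL
  if (config$n_msn2_cells > 0) {
    msn_cfg <- config$sim
    msn_cfg$seed <- seeds[[2]][[1]]
    cells <- stage("msn2", simulate_msn2_cells(msn_cfg, config$n_msn2_cells))
    occupancy <- compute_occupancy(cells$cells, correct_bg = TRUE)
    occupancy$rate <- cells$latent$true_rate[
      match(occupancy$cell_id, cells$latent$cell_id)]
    ok_occ <- occupancy[!is.na(occupancy$occupancy), ]
    occupancy_fit <- stage("occupancy_fit",
      occupancy_growth_regression(ok_occ, occupancy, rate))
    say("occupancy-growth slope %.4g (n=%d cells)",
        glance(occupancy_fit)$slope, nrow(ok_occ))
  }

  survival <- NULL
  if (config$run_heatshock) {
    hs_cfg <- config$sim
    hs_cfg$seed <- seeds[[3]][[1]]
    phases <- stage("heatshock", simulate_heatshock(pop, hs_cfg))
    pre_fit <- fit_population(phases$pre, config$min_points, config$min_r2,
                              quiet = TRUE)
    match <- stage("match", match_lineages(phases$pre, phases$post))
    say("lineage match: %d pairs, shift (%.2f, %.2f), %d+%d unmatched",
        nrow(match$pairs), match$shift[["x"]], match$shift[["y"]],
        length(match$unmatched_pre), length(match$unmatched_post))
    post_cols <- grep("^area_h[0-9]+$", names(phases$post), value = TRUE)
    post_max <- apply(as.matrix(phases$post[, post_cols]), 1, max)
    pre_final <- phases$pre[[sprintf("area_h%d",
      max(as.integer(sub("area_h", "",
        grep("^area_h[0-9]+$", names(phases$pre), value = TRUE)))))]]
    pairs <- match$pairs
    pairs$pre_rate <- pre_fit$rate[match(pairs$pre_id, pre_fit$colony_id)]
    calls <- call_survival(
      pre_final[match(pairs$pre_id, phases$pre$colony_id)],
      post_max[match(pairs$post_id, phases$post$colony_id)])
    pairs <- dplyr::bind_cols(pairs, calls)
    fit <- stage("logistic",
      logistic_survival(pairs[!is.na(pairs$pre_rate), ], pre_rate, alive))
    say("survival logistic: intercept %.3g, slope %.3g (n=%d)",
        fit$coef[[1]], fit$coef[[2]], fit$n)
    survival <- list(phases = phases, match = match, pairs = pairs,
                     fit = fit)
  }

  bundle <- structure(list(
    config = config, pop = pop, fits = fits, scan = thr$scan,
    plateau = thr$plateau, threshold = thr$threshold, filtered = filtered,
    exclusion = excl, contamination = contamination, growth_cdf = growth_cdf,
    reporter_curve = reporter_curve, occupancy = occupancy,
    occupancy_fit = occupancy_fit, survival = survival, log = log
  ), class = "microhet_run")

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(bundle$fits), file.path(dir, "fits.csv"))
  if (!is.null(bundle$scan)) {
    readr::write_csv(as_tibble(bundle$scan), file.path(dir, "scan.csv"))
  }
  readr::write_csv(bundle$exclusion, file.path(dir, "exclusion.csv"))
  readr::write_csv(bundle$growth_cdf, file.path(dir, "growth_cdf.csv"))
  if (!is.null(bundle$occupancy)) {
    readr::write_csv(bundle$occupancy, file.path(dir, "occupancy.csv"))
  }
  if (!is.null(bundle$survival)) {
    readr::write_csv(bundle$survival$pairs, file.path(dir, "survival_pairs.csv"))
  }
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Render a plain-text summary report of a pipeline run
#'
#' Pure rendering: no computation happens here. Missing stages are listed as
#' absent, not fatal.
#'
#' @param bundle A [run_pipeline()] result (possibly partial).
#' @param path Optional file to write; otherwise the text is returned.
#' @return Invisibly, the report lines.
#' @export
make_report <- function(bundle, path = NULL) {
  lines <- c("# microhet run report", "")
  absent <- character(0)
  grab <- function(name, fmt, value) {
    if (is.null(value)) {
      absent <<- c(absent, name)
      NULL
    } else sprintf(fmt, value)
  }
  lines <- c(lines,
    grab("fits", "Colonies fitted: %d", if (is.null(bundle$fits)) NULL else nrow(bundle$fits)),
    grab("threshold", "Selected MitoTracker threshold: %.6g", bundle$threshold),
    if (!is.null(bundle$exclusion)) {
      sprintf("Excluded below threshold: %d of %d (%.2f%%)",
              bundle$exclusion$n_excluded, bundle$exclusion$n_total,
              100 * bundle$exclusion$frac_excluded)
    } else { absent <- c(absent, "exclusion"); NULL },
    if (!is.null(bundle$contamination)) {
      sprintf("Estimated total petite frequency %.4g%%; after-threshold contamination %.4g%%",
              100 * bundle$contamination$p_total,
              100 * bundle$contamination$contamination)
    } else { absent <- c(absent, "contamination"); NULL },
    if (!is.null(bundle$occupancy_fit)) {
      g <- glance(bundle$occupancy_fit)
      sprintf("Occupancy-growth slope %.4g [%.4g, %.4g]",
              g$slope, g$conf_lo, g$conf_hi)
    } else { absent <- c(absent, "occupancy"); NULL },
    if (!is.null(bundle$survival)) {
      sprintf("Survival logistic: intercept %.4g, slope %.4g over %d matched pairs",
              bundle$survival$fit$coef[[1]], bundle$survival$fit$coef[[2]],
              bundle$survival$fit$n)
    } else { absent <- c(absent, "survival"); NULL }
  )
  if (length(absent) > 0) {
    lines <- c(lines, "", paste("Absent stages:", paste(absent, collapse = ", ")))
  }
  if (!is.null(bundle$log) && length(bundle$log) > 0) {
    lines <- c(lines, "", "## Log", bundle$log)
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @export
print.microhet_run <- function(x, ...) {
  cat(paste(make_report(x), collapse = "\n"), "\n")
  invisible(x)
}
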