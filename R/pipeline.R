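#' Run configuration for the full pipeline
#'
#' Bundles the display geometry, experiment design, generator
#' configuration, Bayesian model options and seed that [run_pipeline()]
#' consumes. All defaults are the experiment's values. The object
#' round-trips losslessly through JSON via [jsonlite::toJSON()] with
#' `digits = NA`.
#'
#' @param display A [display_geometry()].
#' @param design An [experiment_design()].
#' @param generator A [generator_config()].
#' @param n_participants Number of synthetic observers.
#' @param seed Integer seed for the generator.
#' @param relief A [relief_prior()] for the Bayesian fit.
#' @param fit_bayes Run the (slower) Bayesian prior fit stage.
#' @return An object of class `"shadow_config"`.
#' @export
shadow_config <- function(display = display_geometry(),
                          design = experiment_design(),
                          generator = generator_config(),
                          n_participants = 25, seed = 1,
                          relief = relief_prior("exponential", scale = 1),
                          fit_bayes = TRUE) {
  structure(list(display = display, design = design, generator = generator,
                 n_participants = n_participants, seed = seed,
                 relief = relief, fit_bayes = fit_bayes),
            class = "shadow_config")
}

#' Simulate, analyze and fit in one pass
#'
#' Runs the full pipeline on one synthetic dataset: generate the trial
#' table, compute the descriptive panel (group fits with and without the
#' control point, mean individual slope, control statistics, direction
#' and blur contrasts), fit the one-parameter GSD model through the
#' origin with its equivalent illumination slant, and (optionally) fit
#' the Bayesian observer's priors to the group means. Identical
#' `(config)` gives identical reports.
#'
#' @param config A [shadow_config()].
#' @return A list of class `"shadow_report"` with elements `trials`
#'   (the simulated table) and `report` (named statistics).
#' @export
run_pipeline <- function(config = shadow_config()) {
  stopifnot(inherits(config, "shadow_config"))
  trials <- generate_dataset(config$generator, config$n_participants,
                             config$seed, config$design)

  group <- group_fit(trials, include_control = TRUE)
  group_shadow <- group_fit(trials, include_control = FALSE)
  cm <- condition_means(trials, by = "offset_dva")
  origin <- fit_through_origin(c(0, cm$offset_dva),
                               c(control_stats(trials)$mean_setting,
                                 cm$mean_setting))
  slopes <- participant_slopes(trials)
  ctrl <- control_stats(trials)

  report <- list(
    n_participants = config$n_participants,
    n_trials = nrow(trials),
    group_slope = group$slope,
    group_intercept = group$intercept,
    group_slope_shadow_only = group_shadow$slope,
    group_intercept_shadow_only = group_shadow$intercept,
    origin_slope = origin$slope,
    equivalent_slant_deg = slant_from_slope(origin$slope),
    mean_participant_slope = mean(slopes$slope),
    participant_slope_range = range(slopes$slope),
    control_zero_fraction = ctrl$zero_fraction,
    control_mean_setting = ctrl$mean_setting,
    direction_contrast_pct = direction_contrast(trials),
    blur_slope_deficit_pct = blur_slope_contrast(trials),
    gsd_rmse = origin$rmse)

  if (isTRUE(config$fit_bayes)) {
    bayes <- fit_priors(cm$offset_dva, cm$mean_setting,
                        relief = config$relief)
    report$bayes_a <- bayes$slant_prior$a
    report$bayes_b <- bayes$slant_prior$b
    report$bayes_prior_mean_slant_deg <- bayes$prior_mean_slant
    report$bayes_rmse <- bayes$rmse
  }

  structure(list(config = config, trials = trials, report = report),
            class = "shadow_report")
}

#' @export
print.shadow_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("Shadow-depth pipeline: %d participants, %d trials\n",
              r$n_participants, r$n_trials))
  cat(sprintf("  group fit (incl. control): slope %.3f, intercept %.3f dva\n",
              r$group_slope, r$group_intercept))
  cat(sprintf("  origin fit: slope %.3f -> equivalent slant %.1f deg\n",
              r$origin_slope, r$equivalent_slant_deg))
  cat(sprintf("  mean individual slope: %.3f (range %.2f-%.2f)\n",
              r$mean_participant_slope, r$participant_slope_range[1],
              r$participant_slope_range[2]))
  cat(sprintf("  control: %.0f%% zeros, mean %.3f dva\n",
              100 * r$control_zero_fraction, r$control_mean_setting))
  cat(sprintf("  contrasts: right-vs-left %+.2f%%, no-blur slope deficit %.2f%%\n",
              r$direction_contrast_pct, r$blur_slope_deficit_pct))
  if (!is.null(r$bayes_prior_mean_slant_deg))
    cat(sprintf("  Bayesian fit: Beta(%.2f, %.2f), prior mean slant %.1f deg, rmse %.3f dva\n",
                r$bayes_a, r$bayes_b, r$bayes_prior_mean_slant_deg,
                r$bayes_rmse))
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' @param x A `"shadow_report"` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "shadow_report"))
  jsonlite::write_json(x$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
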