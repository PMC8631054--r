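#' Method-of-adjustment experiment design
#'
#' The default design crosses 6 shadow offsets, 4 diagonal directions and
#' 3 blur levels with 4 trials per cell, plus 12 no-shadow control trials:
#' 300 trials per participant. The six offsets are equally spaced from
#' 0.14 to 2.16 dva; blur levels are 0.02 (a 1-px point-source shadow),
#' 0.25 and 0.52 dva.
#'
#' @param offsets Shadow offsets, dva.
#' @param directions Diagonal direction labels, see [shadow_directions()].
#' @param blurs Blur-circle diameters, dva; the smallest is treated as the
#'   sharp (no-blur) level.
#' @param trials_per_condition Trials in each offset x direction x blur cell.
#' @param control_trials Number of no-shadow control trials.
#' @return An object of class `"experiment_design"`.
#' @export
experiment_design <- function(offsets = seq(0.14, 2.16, length.out = 6),
                              directions = shadow_directions(),
                              blurs = c(0.02, 0.25, 0.52),
                              trials_per_condition = 4,
                              control_trials = 12) {
  stopifnot(length(offsets) >= 1, all(offsets > 0),
            all(directions %in% shadow_directions()),
            length(blurs) >= 1, all(blurs >= 0),
            trials_per_condition >= 1, control_trials >= 0)
  structure(list(offsets = offsets, directions = directions, blurs = blurs,
                 trials_per_condition = as.integer(trials_per_condition),
                 control_trials = as.integer(control_trials)),
            class = "experiment_design")
}

#' Expand a design into its per-participant trial list
#'
#' One row per trial: every offset x direction x blur cell repeated
#' `trials_per_condition` times, plus the control trials (offset 0,
#' direction and blur `NA`). Row order is the canonical expansion; the
#' generator shuffles it per participant.
#'
#' @param design An [experiment_design()].
#' @return A data frame with columns `offset_dva`, `direction`, `blur_dva`.
#' @export
build_design <- function(design = experiment_design()) {
  stopifnot(inherits(design, "experiment_design"))
  grid <- expand.grid(offset_dva = design$offsets,
                      direction = design$directions,
                      blur_dva = design$blurs,
                      rep = seq_len(design$trials_per_condition),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rep <- NULL
  if (design$control_trials > 0) {
    ctrl <- data.frame(offset_dva = 0, direction = NA_character_,
                       blur_dva = NA_real_)
    grid <- rbind(grid, ctrl[rep(1, design$control_trials), ])
  }
  rownames(grid) <- NULL
  grid
}

#' Synthetic-observer generator configuration
#'
#' Population parameters of the synthetic participants. Defaults reproduce
#' the study's group statistics: mean per-participant depth/offset slope
#' 1.35 with individual slopes truncated to `[0.88, 2.01]`; intercept
#' 0.12 dva; trial noise sd 0.35 dva; no-shadow controls zero with
#' probability 0.54 and otherwise exponential with mean 0.152 dva (so the
#' unconditional control mean is ~0.07 dva); rightward shadows judged
#' 1.6% deeper; the sharp (no-blur) level with a 7.9% shallower slope.
#'
#' Setting the two sd parameters to zero gives a deterministic population
#' at the configured means, useful for exact-recovery checks.
#'
#' @param slope_mean,slope_sd,slope_range Truncated-normal distribution of
#'   per-participant slopes (dimensionless depth/offset ratio).
#' @param intercept_mean,intercept_sd Normal distribution of the
#'   per-participant intercept, dva.
#' @param noise_sd Trial-to-trial setting noise sd, dva.
#' @param control_zero_prob Probability of an exactly-zero control setting.
#' @param control_nonzero_mean Mean of the exponential tail of nonzero
#'   control settings, dva.
#' @param right_gain Multiplicative gain on the (pre-noise) setting for
#'   rightward shadow offsets.
#' @param lower_slope_gain Multiplicative slope gain for lower shadows.
#' @param noblur_slope_gain Multiplicative slope gain for the sharp
#'   (smallest-blur) level.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(slope_mean = 1.35, slope_sd = 0.25,
                             slope_range = c(0.88, 2.01),
                             intercept_mean = 0.12, intercept_sd = 0.08,
                             noise_sd = 0.35,
                             control_zero_prob = 0.54,
                             control_nonzero_mean = 0.152,
                             right_gain = 1.016,
                             lower_slope_gain = 1.0,
                             noblur_slope_gain = 0.921) {
  stopifnot(slope_mean > 0, slope_sd >= 0, length(slope_range) == 2L,
            slope_range[1] > 0, slope_range[2] >= slope_range[1],
            intercept_sd >= 0, noise_sd >= 0,
            control_zero_prob >= 0, control_zero_prob <= 1,
            control_nonzero_mean > 0,
            right_gain > 0, lower_slope_gain > 0, noblur_slope_gain > 0)
  structure(as.list(environment()), class = "generator_config")
}

# inverse-CDF truncated normal; sd = 0 degenerates to the clamped mean
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Draw one synthetic participant
#'
#' Samples a participant's slope (truncated normal) and intercept (normal)
#' from the population in `config`; the remaining fields (noise, control
#' behaviour, direction and blur gains) are shared population constants.
#' Uses the current R random stream; results are deterministic given the
#' stream state.
#'
#' @param config A [generator_config()].
#' @param id Participant identifier.
#' @return An object of class `"participant_model"`.
#' @export
sample_participant <- function(config = generator_config(), id = 1L) {
  stopifnot(inherits(config, "generator_config"))
  slope <- rtruncnorm(1, config$slope_mean, config$slope_sd,
                      config$slope_range[1], config$slope_range[2])
  intercept <- stats::rnorm(1, config$intercept_mean, config$intercept_sd)
  structure(list(id = id, slope = slope, intercept = intercept,
                 noise_sd = config$noise_sd,
                 control_zero_prob = config$control_zero_prob,
                 control_nonzero_mean = config$control_nonzero_mean,
                 right_gain = config$right_gain,
                 lower_slope_gain = config$lower_slope_gain,
                 noblur_slope_gain = config$noblur_slope_gain),
            class = "participant_model")
}

#' Simulate method-of-adjustment depth settings
#'
#' Shadow trials: the deterministic setting is
#' `(intercept + slope_eff * offset) * right_gain^[rightward]` with
#' `slope_eff = slope * lower_slope_gain^[lower] * noblur_slope_gain^[sharp]`;
#' Gaussian trial noise is added and the result floored at zero (the
#' response marker cannot indicate negative depth). Control trials
#' (`direction` `NA`) are zero with probability `control_zero_prob`,
#' otherwise an exponential draw with mean `control_nonzero_mean`.
#'
#' @param participant A [sample_participant()] model.
#' @param offset,direction,blur Parallel vectors describing the trials;
#'   `NA` direction marks a control trial.
#' @param noblur_level The blur value treated as sharp; defaults to the
#'   smallest finite blur present.
#' @return Numeric vector of settings, dva, all `>= 0`.
#' @export
simulate_setting <- function(participant, offset, direction = NA, blur = NA,
                             noblur_level = NULL) {
  stopifnot(inherits(participant, "participant_model"))
  n <- length(offset)
  direction <- rep_len(direction, n)
  blur <- rep_len(blur, n)
  is_control <- is.na(direction)
  if (is.null(noblur_level)) {
    fb <- blur[!is.na(blur)]
    noblur_level <- if (length(fb)) min(fb) else NA_real_
  }
  setting <- numeric(n)

  if (any(!is_control)) {
    i <- which(!is_control)
    right <- direction[i] %in% c("upper-right", "lower-right")
    lower <- direction[i] %in% c("lower-left", "lower-right")
    sharp <- !is.na(blur[i]) & blur[i] == noblur_level
    slope_eff <- participant$slope *
      participant$lower_slope_gain^lower *
      participant$noblur_slope_gain^sharp
    mu <- (participant$intercept + slope_eff * offset[i]) *
      participant$right_gain^right
    setting[i] <- pmax(0, mu + stats::rnorm(length(i), 0,
                                            participant$noise_sd))
  }
  if (any(is_control)) {
    i <- which(is_control)
    zero <- stats::runif(length(i)) < participant$control_zero_prob
    draw <- stats::rexp(length(i), rate = 1 / participant$control_nonzero_mean)
    setting[i] <- ifelse(zero, 0, draw)
  }
  setting
}

#' Generate a full synthetic trial table
#'
#' Draws `n_participants` synthetic observers from `config`, expands the
#' design for each, shuffles the trial order per participant, and
#' simulates every setting. Bit-identical output for identical
#' `(config, design, n_participants, seed)`.
#'
#' @param config A [generator_config()].
#' @param n_participants Number of synthetic observers.
#' @param seed Integer seed.
#' @param design An [experiment_design()].
#' @return A data frame with columns `participant`, `offset_dva`,
#'   `direction`, `blur_dva`, `setting_dva`.
#' @examples
#' trials <- generate_dataset(n_participants = 2, seed = 1)
#' nrow(trials)  # 600
#' @export
generate_dataset <- function(config = generator_config(),
                             n_participants = 25, seed = 1,
                             design = experiment_design()) {
  stopifnot(n_participants >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  base <- build_design(design)
  noblur <- min(design$blurs)
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    model <- sample_participant(config, id = p)
    rows <- base[sample.int(nrow(base)), , drop = FALSE]
    rows$setting_dva <- simulate_setting(model, rows$offset_dva,
                                         rows$direction, rows$blur_dva,
                                         noblur_level = noblur)
    rows <- cbind(participant = p, rows)
    out[[p]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

trial_columns <- c("participant", "offset_dva", "direction", "blur_dva",
                   "setting_dva")

#' Read and write trial tables
#'
#' CSV with header `participant,offset_dva,direction,blur_dva,setting_dva`;
#' control rows leave `direction` and `blur_dva` empty. Numeric columns are
#' written to 6 decimal places, so a round-trip is lossless at that
#' precision. Malformed rows raise an error naming the offending line.
#'
#' @param trials A trial table, e.g. from [generate_dataset()].
#' @param path CSV file path.
#' @return `read_trials()`: the trial table; `write_trials()`: `path`,
#'   invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(trial_columns %in% names(trials)))
  out <- trials[trial_columns]
  for (col in c("offset_dva", "blur_dva", "setting_dva"))
    out[[col]] <- round(out[[col]], 6)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(participant = "character",
                                        offset_dva = "character",
                                        direction = "character",
                                        blur_dva = "character",
                                        setting_dva = "character"))
  if (!identical(names(raw), trial_columns))
    stop("trial CSV must have header: ",
         paste(trial_columns, collapse = ","), call. = FALSE)
  parse_num <- function(x, col, allow_empty = FALSE) {
    empty <- x == ""
    out <- suppressWarnings(as.numeric(x))
    bad <- (is.na(out) & !empty) | (empty & !allow_empty)
    if (any(bad))
      stop(sprintf("malformed value in column '%s' at line %d", col,
                   which(bad)[1] + 1L), call. = FALSE)
    out
  }
  res <- data.frame(
    participant = raw$participant,
    offset_dva = parse_num(raw$offset_dva, "offset_dva"),
    direction = ifelse(raw$direction == "", NA_character_, raw$direction),
    blur_dva = parse_num(raw$blur_dva, "blur_dva", allow_empty = TRUE),
    setting_dva = parse_num(raw$setting_dva, "setting_dva"),
    stringsAsFactors = FALSE)
  bad_dir <- !is.na(res$direction) & !(res$direction %in% shadow_directions())
  if (any(bad_dir))
    stop(sprintf("malformed value in column 'direction' at line %d",
                 which(bad_dir)[1] + 1L), call. = FALSE)
  pnum <- suppressWarnings(as.numeric(res$participant))
  if (!any(is.na(pnum))) res$participant <- pnum
  res
}
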