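#' Condition means of a trial table
#'
#' Two-stage averaging, matching repeated-measures convention: settings
#' are first averaged within each participant for every requested cell,
#' then cell means and standard errors are taken across participants.
#' With `pool = TRUE` all trials are pooled directly instead.
#'
#' @param trials A trial table (see [generate_dataset()]).
#' @param by Cell-defining columns, a subset of
#'   `c("offset_dva", "direction", "blur_dva")`.
#' @param include_control Keep the no-shadow control rows (offset 0).
#' @param pool Pool raw trials instead of two-stage averaging.
#' @return A data frame with the `by` columns plus `mean_setting`, `se`
#'   and `n` (participants, or trials when pooling).
#' @export
condition_means <- function(trials, by = "offset_dva",
                            include_control = FALSE, pool = FALSE) {
  stopifnot(nrow(trials) > 0,
            all(by %in% c("offset_dva", "direction", "blur_dva")))
  if (!include_control) trials <- trials[!is.na(trials$direction), ]
  if (nrow(trials) == 0) stop("no rows left to summarize", call. = FALSE)
  key <- interaction(trials[by], drop = TRUE, lex.order = TRUE, sep = "\r")

  if (pool) {
    agg <- split(trials$setting_dva, key)
  } else {
    per <- tapply(trials$setting_dva,
                  list(key, trials$participant), mean)
    if (anyNA(per))
      warning("some participant x condition cells are empty; omitted")
    agg <- split(per, rownames(per))
    agg <- lapply(agg, function(v) v[!is.na(v)])
  }
  labels <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- as.data.frame(labels, stringsAsFactors = FALSE)
  names(out) <- by
  for (col in intersect(by, c("offset_dva", "blur_dva")))
    out[[col]] <- as.numeric(out[[col]])
  out$mean_setting <- vapply(agg, mean, numeric(1))
  out$se <- vapply(agg, function(v)
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0, numeric(1))
  out$n <- vapply(agg, length, integer(1))
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}

#' No-shadow control statistics
#'
#' The fraction of exactly-zero settings among control trials and the
#' unconditional mean control setting.
#'
#' @param trials A trial table containing control rows (`NA` direction).
#' @return A list with `zero_fraction` and `mean_setting` (dva).
#' @export
control_stats <- function(trials) {
  ctrl <- trials[is.na(trials$direction), ]
  if (nrow(ctrl) == 0) stop("no control rows in the trial table",
                            call. = FALSE)
  list(zero_fraction = mean(ctrl$setting_dva == 0),
       mean_setting = mean(ctrl$setting_dva))
}

#' Rightward-versus-leftward depth contrast
#'
#' Percent increase of mean depth settings for rightward shadow offsets
#' over leftward ones, `100 * (mean_right - mean_left) / mean_left`, with
#' two-stage averaging (participant means first) over shadow trials.
#'
#' @param trials A trial table.
#' @return Percent difference (positive when rightward shadows are judged
#'   deeper).
#' @export
direction_contrast <- function(trials) {
  shadow <- trials[!is.na(trials$direction), ]
  right <- shadow$direction %in% c("upper-right", "lower-right")
  if (!any(right) || all(right))
    stop("both left and right shadow conditions are required", call. = FALSE)
  side_mean <- function(rows) {
    per <- tapply(rows$setting_dva, rows$participant, mean)
    mean(per)
  }
  m_right <- side_mean(shadow[right, ])
  m_left <- side_mean(shadow[!right, ])
  100 * (m_right - m_left) / m_left
}

#' Slope deficit of the sharp (no-blur) shadow
#'
#' Fits a group depth-versus-offset slope per blur level (on two-stage
#' per-offset means) and returns the percent by which the sharp level's
#' slope falls below the average of the two blurred levels':
#' `100 * (1 - slope_sharp / mean(slope_blurred))`.
#'
#' @param trials A trial table containing all three blur levels.
#' @return Percent slope deficit (positive when the sharp shadow yields a
#'   shallower slope).
#' @export
blur_slope_contrast <- function(trials) {
  shadow <- trials[!is.na(trials$direction), ]
  levels <- sort(unique(shadow$blur_dva))
  if (length(levels) < 3)
    stop("all three blur levels are required", call. = FALSE)
  slope_for <- function(blur) {
    rows <- shadow[shadow$blur_dva == blur, ]
    cm <- condition_means(rows, by = "offset_dva")
    fit_line(cm$offset_dva, cm$mean_setting)$slope
  }
  s_sharp <- slope_for(levels[1])
  s_blur <- vapply(levels[-1], slope_for, numeric(1))
  100 * (1 - s_sharp / mean(s_blur))
}

#' Group depth-versus-offset fit
#'
#' [fit_line()] applied to the two-stage per-offset group means; with
#' `include_control = TRUE` the control mean enters as an offset-0 point.
#'
#' @param trials A trial table.
#' @param include_control Append the control mean at offset 0.
#' @return A `"gsd_fit"`.
#' @export
group_fit <- function(trials, include_control = FALSE) {
  cm <- condition_means(trials, by = "offset_dva")
  x <- cm$offset_dva; y <- cm$mean_setting
  if (include_control) {
    cs <- control_stats(trials)
    x <- c(0, x); y <- c(cs$mean_setting, y)
  }
  fit_line(x, y)
}
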