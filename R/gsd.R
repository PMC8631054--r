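#' The generic shadow-to-depth (GSD) linear model
#'
#' Perceived depth is modelled as a fixed linear multiple of the shadow
#' offset. Geometrically, a constant depth/offset slope `k` is equivalent
#' to assuming a single generic illumination slant `atan(1/k)`
#' ([slant_from_slope()]); the one-parameter form pins the intercept at
#' zero so that zero offset yields zero depth.
#'
#' `fit_line()` is ordinary least squares with a free intercept;
#' `fit_through_origin()` is the one-parameter model,
#' `slope = sum(x*y) / sum(x^2)`. Both return a `"gsd_fit"` object with
#' `print`, `summary`, `coef`, `predict`, `residuals`, `fitted` and `plot`
#' methods; `summary()` also reports the equivalent illumination slant.
#'
#' @param offsets Shadow offsets, dva.
#' @param depths Matched depth settings, dva.
#' @return An object of class `"gsd_fit"`: a list with elements `slope`,
#'   `intercept`, `slope_se`, `intercept_se`, `rmse`, `n`, `pinned`,
#'   `offsets`, `depths`, `fitted`, `residuals`.
#' @examples
#' o <- seq(0.14, 2.16, length.out = 6)
#' fit <- fit_line(o, 0.12 + 1.31 * o)
#' coef(fit)
#' summary(fit_through_origin(o, 1.4 * o))
#' @export
fit_line <- function(offsets, depths) {
  check_xy(offsets, depths, min_n = 3)
  if (max(offsets) - min(offsets) <= 0)
    stop("offsets are degenerate (all equal); cannot fit a line",
         call. = FALSE)
  fit <- stats::lm(depths ~ offsets)
  # exact (zero-residual) fits are legitimate here; silence summary.lm's
  # "essentially perfect fit" caution
  cf <- suppressWarnings(summary(fit)$coefficients)
  new_gsd_fit(slope = cf["offsets", 1], intercept = cf["(Intercept)", 1],
              slope_se = cf["offsets", 2], intercept_se = cf["(Intercept)", 2],
              offsets = offsets, depths = depths, pinned = FALSE)
}

#' @rdname fit_line
#' @export
fit_through_origin <- function(offsets, depths) {
  check_xy(offsets, depths, min_n = 2)
  if (all(offsets == 0))
    stop("all offsets are zero; slope through the origin is undefined",
         call. = FALSE)
  fit <- stats::lm(depths ~ offsets + 0)
  cf <- suppressWarnings(summary(fit)$coefficients)
  new_gsd_fit(slope = cf["offsets", 1], intercept = 0,
              slope_se = cf["offsets", 2], intercept_se = NA_real_,
              offsets = offsets, depths = depths, pinned = TRUE)
}

check_xy <- function(x, y, min_n) {
  if (length(x) != length(y))
    stop("'offsets' and 'depths' must have equal length", call. = FALSE)
  if (length(x) < min_n)
    stop(sprintf("need at least %d points", min_n), call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in the data", call. = FALSE)
  invisible(NULL)
}

new_gsd_fit <- function(slope, intercept, slope_se, intercept_se,
                        offsets, depths, pinned) {
  fitted <- intercept + slope * offsets
  res <- depths - fitted
  structure(list(slope = unname(slope), intercept = unname(intercept),
                 slope_se = unname(slope_se),
                 intercept_se = unname(intercept_se),
                 rmse = sqrt(mean(res^2)), n = length(offsets),
                 pinned = pinned, offsets = offsets, depths = depths,
                 fitted = fitted, residuals = res),
            class = "gsd_fit")
}

#' @export
print.gsd_fit <- function(x, digits = 4, ...) {
  cat(if (x$pinned) "GSD fit through the origin\n" else "GSD linear fit\n")
  cat(sprintf("  slope: %.*f  intercept: %.*f dva  rmse: %.*f dva  n = %d\n",
              digits, x$slope, digits, x$intercept, digits, x$rmse, x$n))
  invisible(x)
}

#' @export
summary.gsd_fit <- function(object, ...) {
  coefs <- rbind(
    intercept = c(Estimate = object$intercept, `Std. Error` = object$intercept_se),
    slope = c(Estimate = object$slope, `Std. Error` = object$slope_se))
  if (object$pinned) coefs <- coefs["slope", , drop = FALSE]
  out <- list(coefficients = coefs, rmse = object$rmse, n = object$n,
              pinned = object$pinned,
              equivalent_slant = if (object$slope > 0)
                slant_from_slope(object$slope) else NA_real_)
  class(out) <- "summary.gsd_fit"
  out
}

#' @export
print.summary.gsd_fit <- function(x, digits = 4, ...) {
  cat(if (x$pinned) "GSD fit through the origin\n" else "GSD linear fit\n")
  print(round(x$coefficients, digits))
  cat(sprintf("rmse: %.*f dva over %d points\n", digits, x$rmse, x$n))
  cat(sprintf("equivalent illumination slant: %.1f degrees\n",
              x$equivalent_slant))
  invisible(x)
}

#' @export
coef.gsd_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.gsd_fit <- function(object, offsets = NULL, ...) {
  if (is.null(offsets)) return(object$fitted)
  object$intercept + object$slope * offsets
}

#' @export
residuals.gsd_fit <- function(object, ...) object$residuals

#' @export
fitted.gsd_fit <- function(object, ...) object$fitted

#' @export
plot.gsd_fit <- function(x, xlab = "shadow offset (dva)",
                         ylab = "depth setting (dva)", ...) {
  graphics::plot(x$offsets, x$depths, xlab = xlab, ylab = ylab, ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Per-participant depth/offset slope
#'
#' Fits the linear model to one participant's condition means at each
#' shadow offset (means over direction, blur and repeats). The no-shadow
#' control is excluded by default, matching the convention for individual
#' slopes; with `include_control = TRUE` the control mean enters as an
#' offset-0 point.
#'
#' @param trials Trial table rows for a single participant.
#' @param include_control Include the control mean as an x = 0 point.
#' @return A `"gsd_fit"` on the per-offset means.
#' @export
participant_slope <- function(trials, include_control = FALSE) {
  stopifnot(all(c("offset_dva", "direction", "setting_dva") %in% names(trials)))
  if (length(unique(trials$participant)) > 1)
    stop("'trials' must contain a single participant", call. = FALSE)
  shadow <- trials[!is.na(trials$direction), ]
  means <- tapply(shadow$setting_dva, shadow$offset_dva, mean)
  x <- as.numeric(names(means)); y <- as.numeric(means)
  if (include_control) {
    ctrl <- trials[is.na(trials$direction), ]
    if (nrow(ctrl) > 0) {
      x <- c(0, x); y <- c(mean(ctrl$setting_dva), y)
    }
  }
  if (length(unique(x)) < 3)
    stop("need settings at >= 3 distinct offsets", call. = FALSE)
  fit_line(x, y)
}

#' Slopes for every participant in a trial table
#'
#' @param trials A full trial table.
#' @inheritParams participant_slope
#' @return A data frame with one row per participant: `participant`,
#'   `slope`, `intercept`, `rmse`.
#' @export
participant_slopes <- function(trials, include_control = FALSE) {
  ids <- unique(trials$participant)
  fits <- lapply(ids, function(p)
    participant_slope(trials[trials$participant == p, ], include_control))
  data.frame(participant = ids,
             slope = vapply(fits, `[[`, numeric(1), "slope"),
             intercept = vapply(fits, `[[`, numeric(1), "intercept"),
             rmse = vapply(fits, `[[`, numeric(1), "rmse"))
}
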