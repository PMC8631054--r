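#' Priors of the Bayesian shadow-depth observer
#'
#' The observer is uncertain about the illumination slant; a two-parameter
#' beta distribution over `slant/90` encodes that uncertainty
#' (`slant_prior()`). A second prior over scene relief (`relief_prior()`)
#' encodes how much object-background separation is expected a priori:
#' either flat on `[0, d_max]` or exponential with a given scale,
#' favouring small reliefs.
#'
#' @param a,b Beta shape parameters, both `> 0`. `a = b = 1` is the flat
#'   slant prior.
#' @return `slant_prior()`: an object of class `"slant_prior"`.
#' @examples
#' prior_mean_slant(slant_prior(3, 4))  # 90 * 3/7
#' @export
slant_prior <- function(a = 1, b = 1) {
  stopifnot(is.numeric(a), is.numeric(b), a > 0, b > 0)
  structure(list(a = a, b = b), class = "slant_prior")
}

#' @rdname slant_prior
#' @param slant Illumination slant, degrees in `[0, 90]`.
#' @param prior A [slant_prior()].
#' @return `slant_prior_pdf()`: density per degree of slant.
#' @export
slant_prior_pdf <- function(slant, prior = slant_prior()) {
  stopifnot(inherits(prior, "slant_prior"))
  if (any(!is.finite(slant)) || any(slant < 0) || any(slant > 90))
    stop("'slant' must lie in [0, 90] degrees", call. = FALSE)
  stats::dbeta(slant / 90, prior$a, prior$b) / 90
}

#' @rdname slant_prior
#' @return `prior_mean_slant()`: the prior mean slant `90 * a / (a + b)`
#'   in degrees.
#' @export
prior_mean_slant <- function(prior) {
  stopifnot(inherits(prior, "slant_prior"))
  90 * prior$a / (prior$a + prior$b)
}

#' @rdname slant_prior
#' @param kind `"flat"` (uniform on `[0, d_max]`) or `"exponential"`
#'   (density `exp(-d/scale)/scale` on `[0, Inf)`).
#' @param d_max Upper support bound of the flat relief prior, dva.
#' @param scale Scale of the exponential relief prior, dva.
#' @return `relief_prior()`: an object of class `"relief_prior"`.
#' @export
relief_prior <- function(kind = c("flat", "exponential"), d_max = 50,
                         scale = 1) {
  kind <- match.arg(kind)
  stopifnot(d_max > 0, scale > 0)
  structure(list(kind = kind, d_max = d_max, scale = scale),
            class = "relief_prior")
}

#' @rdname slant_prior
#' @param depth Relief (object-background separation), dva.
#' @return `relief_pdf()`: density per dva of relief.
#' @export
relief_pdf <- function(depth, prior = relief_prior()) {
  stopifnot(inherits(prior, "relief_prior"))
  if (prior$kind == "flat")
    ifelse(depth >= 0 & depth <= prior$d_max, 1 / prior$d_max, 0)
  else
    stats::dexp(pmax(depth, 0), rate = 1 / prior$scale) * (depth >= 0)
}

#' Likelihood of a shadow offset given depth
#'
#' With offset-measurement noise negligible, all uncertainty about the
#' offset expected from a given depth comes from the unknown illumination
#' slant; the likelihood is the slant prior pushed through the projection
#' `o = d * tan(sigma)`:
#' `p(o | d) = p_slant(atan(o/d)) * (180/pi) * d / (d^2 + o^2)`
#' with `p_slant` per degree, so `p(o | d)` is per dva of offset. For
#' fixed `d` it integrates to 1 over `o` in `(0, Inf)` when the slant
#' prior is proper, and satisfies the scaling identity
#' `likelihood(c*o, c*d) = likelihood(o, d)/c`.
#'
#' @param offset Observed shadow offset, dva, `> 0` (vectorized).
#' @param depth Hypothesised depth, dva, `> 0`.
#' @param prior A [slant_prior()].
#' @return Likelihood density per dva of offset.
#' @export
shadow_likelihood <- function(offset, depth, prior = slant_prior()) {
  if (any(depth <= 0))
    stop("'depth' must be > 0 in the likelihood", call. = FALSE)
  if (any(offset < 0))
    stop("'offset' must be >= 0", call. = FALSE)
  sl <- rad2deg(atan(offset / depth))
  slant_prior_pdf(sl, prior) * (180 / pi) * depth / (depth^2 + offset^2)
}

# depth grid covering both the likelihood's scale (tracks the offset) and
# the relief prior's support
posterior_grid_nodes <- function(offset, relief, n_grid = 2000, span = 100) {
  upper_prior <- if (relief$kind == "flat") relief$d_max else 20 * relief$scale
  lo <- offset / span
  hi <- max(offset * span, upper_prior)
  exp(seq(log(lo), log(hi), length.out = n_grid))
}

#' Posterior over depth given a shadow offset
#'
#' Discretized posterior `p(d | o) \propto p(o | d) * p_relief(d)` on a
#' geometric depth grid spanning `[offset/span, max(offset*span, prior
#' support bound)]`, normalized under the trapezoid rule so the returned
#' weights sum to 1.
#'
#' @param offset Observed shadow offset, dva, `> 0`.
#' @param slant_prior A [slant_prior()].
#' @param relief A [relief_prior()].
#' @param n_grid Number of depth nodes (`>= 200`).
#' @param span Grid span factor relative to the offset.
#' @return An object of class `"posterior_grid"`: list with `depth`
#'   (nodes, dva) and `weight` (nonnegative, summing to 1), plus the
#'   inputs.
#' @export
depth_posterior <- function(offset, slant_prior = shadowdepth::slant_prior(),
                            relief = relief_prior(), n_grid = 2000,
                            span = 100) {
  stopifnot(length(offset) == 1L, offset > 0, n_grid >= 200)
  d <- posterior_grid_nodes(offset, relief, n_grid, span)
  dens <- shadow_likelihood(offset, d, slant_prior) * relief_pdf(d, relief)
  # trapezoid quadrature weights on the irregular grid
  dd <- diff(d)
  quad <- c(dd[1] / 2, (dd[-1] + dd[-length(dd)]) / 2, dd[length(dd)] / 2)
  w <- dens * quad
  total <- sum(w)
  if (!is.finite(total) || total <= 0)
    stop("posterior mass vanished; check priors and offset", call. = FALSE)
  structure(list(depth = d, weight = w / total, offset = offset,
                 slant_prior = slant_prior, relief = relief),
            class = "posterior_grid")
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat(sprintf("Depth posterior for offset %.3f dva on %d nodes\n",
              x$offset, length(x$depth)))
  cat(sprintf("  mean %.4f dva, mode %.4f dva\n",
              sum(x$depth * x$weight), x$depth[which.max(x$weight)]))
  invisible(x)
}

#' Posterior-mean depth estimate
#'
#' The squared-error-optimal depth readout: the mean of the posterior from
#' [depth_posterior()]. A zero offset carries no separation signal and
#' returns depth 0 by convention, matching the predominantly flat
#' judgments of the no-shadow control.
#'
#' @inheritParams depth_posterior
#' @param offset Shadow offsets, dva, `>= 0` (vectorized).
#' @return Posterior-mean depths, dva.
#' @export
posterior_mean_depth <- function(offset,
                                 slant_prior = shadowdepth::slant_prior(),
                                 relief = relief_prior(), n_grid = 2000,
                                 span = 100) {
  vapply(offset, function(o) {
    if (o == 0) return(0)
    post <- depth_posterior(o, slant_prior, relief, n_grid, span)
    sum(post$depth * post$weight)
  }, numeric(1))
}

#' Fit the Bayesian observer's priors to depth judgments
#'
#' Finds the beta slant-prior parameters (and optionally the exponential
#' relief scale) that minimize the sum of squared differences between the
#' model's posterior-mean depths and observed mean depth settings at the
#' given offsets. Derivative-free Nelder-Mead search on log-parameters
#' from a multistart grid `(a, b) in {1, 2, 4}^2`; ties broken by lower
#' RMSE, then lower `a + b`.
#'
#' @param offsets Shadow offsets, dva, `> 0`, at least 3.
#' @param depths Observed mean depth settings, dva.
#' @param relief A [relief_prior()]; its parameters are held fixed unless
#'   `fit_relief_scale = TRUE` (exponential kind only).
#' @param fit_relief_scale Also fit the exponential relief scale.
#' @param n_grid,span Posterior grid settings, see [depth_posterior()].
#' @param starts Matrix (or data frame) of `(a, b)` start values.
#' @param maxit Nelder-Mead iteration budget per start.
#' @return An object of class `"shadow_bayes"`: fitted `slant_prior`,
#'   `relief`, `prior_mean_slant` (degrees), `rmse` (dva), `fitted`,
#'   `residuals`, the data, and optimizer diagnostics. Methods: `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `fitted`, `plot`.
#' @examples
#' \donttest{
#' o <- seq(0.14, 2.16, length.out = 6)
#' d <- posterior_mean_depth(o, slant_prior(3, 4))
#' fit <- fit_priors(o, d)
#' summary(fit)
#' }
#' @export
fit_priors <- function(offsets, depths, relief = relief_prior(),
                       fit_relief_scale = FALSE, n_grid = 2000, span = 100,
                       starts = as.matrix(expand.grid(a = c(1, 2, 4),
                                                      b = c(1, 2, 4))),
                       maxit = 400) {
  check_xy(offsets, depths, min_n = 3)
  if (any(offsets <= 0))
    stop("'offsets' must be > 0 for prior fitting", call. = FALSE)
  if (fit_relief_scale && relief$kind != "exponential")
    stop("'fit_relief_scale' requires an exponential relief prior",
         call. = FALSE)

  objective <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    rel <- relief
    if (fit_relief_scale) rel$scale <- exp(par[3])
    pred <- posterior_mean_depth(offsets, slant_prior(a, b), rel,
                                 n_grid = n_grid, span = span)
    sum((pred - depths)^2)
  }

  best <- NULL
  any_converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    par0 <- log(c(starts[i, 1], starts[i, 2],
                  if (fit_relief_scale) relief$scale))
    opt <- stats::optim(par0, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    any_converged <- any_converged || opt$convergence == 0
    if (is.null(best) || opt$value < best$value - 1e-12 ||
        (abs(opt$value - best$value) <= 1e-12 &&
         sum(exp(opt$par[1:2])) < sum(exp(best$par[1:2]))))
      best <- opt
  }
  a <- unname(exp(best$par[1])); b <- unname(exp(best$par[2]))
  rel <- relief
  if (fit_relief_scale) rel$scale <- unname(exp(best$par[3]))
  sp <- slant_prior(a, b)
  fitted <- posterior_mean_depth(offsets, sp, rel, n_grid = n_grid,
                                 span = span)
  res <- depths - fitted
  out <- structure(list(slant_prior = sp, relief = rel,
                        prior_mean_slant = prior_mean_slant(sp),
                        rmse = sqrt(mean(res^2)),
                        offsets = offsets, depths = depths,
                        fitted = fitted, residuals = res,
                        n_grid = n_grid, span = span,
                        fit_relief_scale = fit_relief_scale,
                        convergence = best$convergence,
                        objective = best$value),
                   class = "shadow_bayes")
  if (!any_converged)
    stop(paste0("prior fit did not converge within the iteration budget; ",
                sprintf("best so far a = %.3f, b = %.3f, rmse = %.4f",
                        a, b, out$rmse)), call. = FALSE)
  out
}

#' @export
print.shadow_bayes <- function(x, digits = 4, ...) {
  cat("Bayesian shadow-depth observer fit\n")
  cat(sprintf("  slant prior: Beta(%.3f, %.3f), mean slant %.1f deg\n",
              x$slant_prior$a, x$slant_prior$b, x$prior_mean_slant))
  cat(sprintf("  relief prior: %s (%s)\n", x$relief$kind,
              if (x$relief$kind == "flat")
                sprintf("d_max = %.3g dva", x$relief$d_max)
              else sprintf("scale = %.3g dva", x$relief$scale)))
  cat(sprintf("  rmse: %.*f dva over %d offsets\n", digits, x$rmse,
              length(x$offsets)))
  invisible(x)
}

#' @export
summary.shadow_bayes <- function(object, ...) {
  structure(list(fit = object), class = "summary.shadow_bayes")
}

#' @export
print.summary.shadow_bayes <- function(x, ...) {
  print(x$fit)
  tab <- data.frame(offset_dva = x$fit$offsets,
                    observed = x$fit$depths,
                    predicted = x$fit$fitted,
                    residual = x$fit$residuals)
  print(format(tab, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.shadow_bayes <- function(object, ...) {
  out <- c(a = object$slant_prior$a, b = object$slant_prior$b,
           prior_mean_slant = object$prior_mean_slant)
  if (object$fit_relief_scale) out <- c(out, relief_scale = object$relief$scale)
  out
}

#' @export
predict.shadow_bayes <- function(object, offsets = NULL, ...) {
  if (is.null(offsets)) return(object$fitted)
  posterior_mean_depth(offsets, object$slant_prior, object$relief,
                       n_grid = object$n_grid, span = object$span)
}

#' @export
residuals.shadow_bayes <- function(object, ...) object$residuals

#' @export
fitted.shadow_bayes <- function(object, ...) object$fitted

#' @export
plot.shadow_bayes <- function(x, xlab = "shadow offset (dva)",
                              ylab = "depth (dva)", ...) {
  graphics::plot(x$offsets, x$depths, xlab = xlab, ylab = ylab, ...)
  o <- seq(min(x$offsets), max(x$offsets), length.out = 50)
  graphics::lines(o, predict(x, o))
  invisible(x)
}
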