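test_that("slant prior density and mean follow the scaled beta", {
  expect_equal(slant_prior_pdf(45, slant_prior(1, 1)), 1 / 90,
               tolerance = 1e-12)
  expect_equal(slant_prior_pdf(0, slant_prior(2, 2)), 0)
  expect_equal(slant_prior_pdf(45, slant_prior(2, 2)), 1.5 / 90,
               tolerance = 1e-12)
  expect_error(slant_prior_pdf(91, slant_prior(2, 2)), "\\[0, 90\\]")
  expect_error(slant_prior(0, 1), "a > 0")

  # density integrates to 1 over [0, 90] degrees
  s <- seq(0, 90, length.out = 20001)
  f <- slant_prior_pdf(s, slant_prior(2.7, 3.1))
  expect_equal(sum((f[-1] + f[-length(f)]) / 2) * diff(s)[1], 1,
               tolerance = 1e-6)

  expect_equal(prior_mean_slant(slant_prior(1, 1)), 45)
  expect_equal(prior_mean_slant(slant_prior(2, 2)), 45)
  expect_equal(prior_mean_slant(slant_prior(3, 4)), 90 * 3 / 7,
               tolerance = 1e-12)
})

test_that("likelihood is the slant prior under change of variables", {
  # closed-form composition at d = o = 1 under the flat prior
  expect_equal(shadow_likelihood(1, 1), (1 / 90) * (180 / pi) * 0.5,
               tolerance = 1e-12)
  # scaling identity: doubling offset and depth halves the density
  for (prior in list(slant_prior(1, 1), slant_prior(3, 4))) {
    expect_equal(shadow_likelihood(2, 2, prior),
                 shadow_likelihood(1, 1, prior) / 2, tolerance = 1e-12)
    expect_equal(shadow_likelihood(0.6, 1.5, prior),
                 shadow_likelihood(0.2, 0.5, prior) / 3, tolerance = 1e-12)
  }
  expect_error(shadow_likelihood(1, 0), "depth")
  expect_error(shadow_likelihood(-1, 1), "offset")
})

test_that("likelihood integrates to one over all offsets", {
  d <- 1
  # flat prior has slant mass arbitrarily close to 90 degrees, i.e. very
  # large offsets; integrate far enough to capture it
  o <- exp(seq(log(1e-6), log(1e4), length.out = 200001))
  f <- shadow_likelihood(o, d)
  expect_equal(sum((f[-1] + f[-length(f)]) / 2 * diff(o)), 1,
               tolerance = 1e-3)
  # an interior prior concentrates mass at moderate offsets
  o2 <- seq(1e-6, 100, length.out = 200001)
  f2 <- shadow_likelihood(o2, d, slant_prior(2, 2))
  expect_equal(sum(f2) * diff(o2)[1], 1, tolerance = 1e-3)
})

test_that("posterior grids are normalized and well-shaped", {
  for (o in c(0.14, 1, 2.16)) {
    post <- depth_posterior(o, slant_prior(3, 4),
                            relief_prior("exponential", scale = 1))
    expect_equal(sum(post$weight), 1, tolerance = 1e-6)
    expect_true(all(post$weight >= 0))
    expect_gte(length(post$depth), 200)
    expect_true(all(diff(post$depth) > 0))
  }
  expect_error(depth_posterior(1, n_grid = 50), "n_grid")
})

test_that("a concentrated slant prior reduces to the fixed-slant geometry", {
  for (s0 in c(30, 35.5, 60)) {
    m <- s0 / 90; k <- 2e4
    prior <- slant_prior(k * m, k * (1 - m))
    post <- depth_posterior(1, prior, relief_prior("flat", 100))
    truth <- depth_from_offset(1, s0)
    mode <- post$depth[which.max(post$weight)]
    step <- diff(post$depth)[which.max(post$weight)]
    expect_lt(abs(mode - truth), 2 * step)
    est <- posterior_mean_depth(1, prior, relief_prior("flat", 100))
    expect_lt(abs(est - truth) / truth, 0.01)
  }
})

test_that("posterior mean matches a dense brute-force quadrature", {
  rel <- relief_prior("flat", 50)
  est <- posterior_mean_depth(1, slant_prior(1, 1), rel)
  d <- seq(1e-4, 50, length.out = 4e5)
  dens <- shadow_likelihood(1, d) * relief_pdf(d, rel)
  oracle <- sum(d * dens) / sum(dens)
  expect_lt(abs(est - oracle) / oracle, 1e-3)

  rel2 <- relief_prior("exponential", scale = 1)
  est2 <- posterior_mean_depth(0.7, slant_prior(3, 4), rel2)
  d2 <- seq(1e-5, 40, length.out = 4e5)
  dens2 <- shadow_likelihood(0.7, d2, slant_prior(3, 4)) * relief_pdf(d2, rel2)
  oracle2 <- sum(d2 * dens2) / sum(dens2)
  expect_lt(abs(est2 - oracle2) / oracle2, 1e-3)
})

test_that("posterior mean is zero at zero offset and increasing beyond", {
  prior <- slant_prior(3, 4)
  rel <- relief_prior("exponential", scale = 1)
  expect_identical(posterior_mean_depth(0, prior, rel), 0)
  est <- posterior_mean_depth(seq(0.1, 3, by = 0.1), prior, rel)
  expect_true(all(diff(est) > 0))
})

test_that("a wide flat relief prior makes the estimate linear in offset", {
  offs <- paper_offsets()
  rel <- relief_prior("flat", 1000)
  for (prior in list(slant_prior(3, 4), slant_prior(4, 4))) {
    ratio <- posterior_mean_depth(offs, prior, rel) / offs
    expect_lt((max(ratio) - min(ratio)) / mean(ratio), 0.02)
    # scale invariance: doubling the offset doubles the estimate
    e1 <- posterior_mean_depth(1, prior, rel)
    e2 <- posterior_mean_depth(2, prior, rel)
    expect_lt(abs(e2 - 2 * e1) / (2 * e1), 0.02)
  }
})

test_that("prior fitting recovers a known generating prior", {
  offs <- paper_offsets()
  rel <- relief_prior("flat", 50)
  truth <- slant_prior(3, 4)
  d <- posterior_mean_depth(offs, truth, rel)
  fit <- fit_priors(offs, d, rel)
  expect_lt(abs(fit$prior_mean_slant - prior_mean_slant(truth)), 3)
  expect_lt(fit$rmse, 0.01)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(unname(coef(fit)["prior_mean_slant"]), fit$prior_mean_slant)
  expect_output(print(fit), "Beta")
  expect_output(print(summary(fit)), "predicted")
})

test_that("on linear data the Bayesian fit reproduces the GSD line", {
  offs <- paper_offsets()
  fit <- fit_priors(offs, 1.4 * offs, relief_prior("exponential", scale = 1))
  expect_lt(max(abs(fitted(fit) - 1.4 * offs)), 0.01)
  # the fitted prior's mean slant matches the line's equivalent slant
  expect_lt(abs(fit$prior_mean_slant - slant_from_slope(1.4)), 3)
})
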