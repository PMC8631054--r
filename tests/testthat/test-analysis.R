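constant_trials <- function(settings_by_participant) {
  base <- build_design(experiment_design(trials_per_condition = 1,
                                         control_trials = 2))
  out <- lapply(seq_along(settings_by_participant), function(p) {
    rows <- base
    rows$setting_dva <- settings_by_participant[[p]]
    cbind(participant = p, rows)
  })
  do.call(rbind, out)
}

test_that("two-stage condition means average participants equally", {
  # one participant with constant settings
  t1 <- constant_trials(list(rep(2, 74)))
  cm <- condition_means(t1, by = "offset_dva")
  expect_equal(cm$mean_setting, rep(2, 6))
  expect_equal(cm$se, rep(0, 6))
  expect_equal(cm$n, rep(1L, 6))

  # two participants with means 1 and 3 -> grand mean 2
  t2 <- constant_trials(list(rep(1, 74), rep(3, 74)))
  cm2 <- condition_means(t2, by = "offset_dva")
  expect_equal(cm2$mean_setting, rep(2, 6))
  expect_equal(cm2$n, rep(2L, 6))

  # duplicating one participant's rows changes nothing (two-stage)
  dup <- rbind(t2, t2[t2$participant == 2, ])
  expect_equal(condition_means(dup, by = "offset_dva")$mean_setting,
               cm2$mean_setting)
  # pooling, by contrast, is weight-sensitive
  expect_false(isTRUE(all.equal(
    condition_means(dup, by = "offset_dva", pool = TRUE)$mean_setting,
    cm2$mean_setting)))
})

test_that("condition means respect the requested cell structure", {
  trials <- generate_dataset(n_participants = 3, seed = 14)
  cm <- condition_means(trials, by = c("offset_dva", "blur_dva"))
  expect_equal(nrow(cm), 18)
  expect_true(all(cm$n == 3))
  cmd <- condition_means(trials, by = c("offset_dva", "direction"))
  expect_equal(nrow(cmd), 24)
  expect_true(all(cmd$direction %in% shadow_directions()))
})

test_that("control statistics count exact zeros and the raw mean", {
  trials <- data.frame(participant = 1,
                       offset_dva = 0,
                       direction = NA_character_,
                       blur_dva = NA_real_,
                       setting_dva = c(0, 0, 0.2, 0.2))
  cs <- control_stats(trials)
  expect_equal(cs$zero_fraction, 0.5)
  expect_equal(cs$mean_setting, 0.1)

  all_zero <- trials; all_zero$setting_dva <- 0
  expect_equal(control_stats(all_zero), list(zero_fraction = 1,
                                             mean_setting = 0))
  shadow_only <- trials; shadow_only$direction <- "upper-left"
  expect_error(control_stats(shadow_only), "control")
})

test_that("direction contrast is definitional and vanishes for equal sides", {
  t2 <- constant_trials(list(rep(1, 74)))
  expect_equal(direction_contrast(t2), 0)

  t3 <- t2
  right <- !is.na(t3$direction) &
    t3$direction %in% c("upper-right", "lower-right")
  t3$setting_dva[right] <- 1.016
  expect_equal(direction_contrast(t3), 1.6, tolerance = 1e-9)

  only_left <- t2[!is.na(t2$direction) &
                    t2$direction %in% c("upper-left", "lower-left"), ]
  expect_error(direction_contrast(only_left), "left and right")
})

test_that("blur slope contrast is definitional and vanishes when equal", {
  base <- constant_trials(list(rep(0, 74)))
  shadow <- !is.na(base$direction)
  base$setting_dva[shadow] <- base$offset_dva[shadow]  # slope 1 at all blurs
  expect_equal(blur_slope_contrast(base), 0, tolerance = 1e-9)

  t2 <- base
  sharp <- shadow & base$blur_dva == 0.02
  t2$setting_dva[sharp] <- 0.921 * t2$offset_dva[sharp]
  expect_equal(blur_slope_contrast(t2), 7.9, tolerance = 1e-9)

  missing <- t2[!(shadow & t2$blur_dva == 0.52), ]
  expect_error(blur_slope_contrast(missing), "blur levels")
})

test_that("noiseless generation reproduces the configured panel exactly", {
  cfg <- noiseless_config(slope = 1.35, intercept = 0.12,
                          right_gain = 1.016, noblur_slope_gain = 0.921,
                          control_zero_prob = 1)
  trials <- generate_dataset(cfg, n_participants = 5, seed = 77)

  expect_equal(control_stats(trials), list(zero_fraction = 1,
                                           mean_setting = 0))
  expect_equal(mean(participant_slopes(trials)$slope),
               1.35 * (0.921 + 1 + 1) / 3 * (1 + 1.016) / 2,
               tolerance = 1e-9)
  expect_equal(blur_slope_contrast(trials), 7.9, tolerance = 1e-6)
  # the lateral gain multiplies the whole deterministic setting
  expect_equal(direction_contrast(trials), 1.6, tolerance = 1e-9)

  # with unit gains every contrast vanishes
  flat <- generate_dataset(noiseless_config(slope = 1.2, intercept = 0.1),
                           n_participants = 3, seed = 78)
  expect_equal(direction_contrast(flat), 0, tolerance = 1e-12)
  expect_equal(blur_slope_contrast(flat), 0, tolerance = 1e-9)
  g <- group_fit(flat, include_control = FALSE)
  expect_equal(g$slope, 1.2, tolerance = 1e-9)
  expect_equal(g$intercept, 0.1, tolerance = 1e-9)
})

test_that("group fit appends the control as an offset-zero mean", {
  cfg <- noiseless_config(slope = 1.4, intercept = 0, control_zero_prob = 1)
  trials <- generate_dataset(cfg, n_participants = 2, seed = 80)
  g <- group_fit(trials, include_control = TRUE)
  expect_equal(g$n, 7)
  expect_equal(g$slope, 1.4, tolerance = 1e-9)
  expect_equal(g$intercept, 0, tolerance = 1e-9)
})
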