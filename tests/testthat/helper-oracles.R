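# Independent oracles, kept deliberately naive.

# OLS by the closed-form normal equations (2x2 solve), with textbook SEs.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  det <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / det
  intercept <- (sy * sxx - sx * sxy) / det
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(s2 * n / det),
       intercept_se = sqrt(s2 * sxx / det))
}

# regression through the origin by direct summation
origin_oracle <- function(x, y) sum(x * y) / sum(x^2)

# brute-force pixel count of the L-shaped shadow region: loop over every
# pixel of an s x s square shifted by (dx, dy), count those not covered
# by the unshifted square
brute_shadow_area <- function(s, dx, dy) {
  count <- 0L
  for (i in seq_len(s)) {
    for (j in seq_len(s)) {
      ii <- i + dy; jj <- j + dx
      inside_square <- ii >= 1 && ii <= s && jj >= 1 && jj <= s
      if (!inside_square) count <- count + 1L
    }
  }
  count
}

# deterministic population: every sampled participant equals the means
noiseless_config <- function(slope = 1.35, intercept = 0.12,
                             right_gain = 1, lower_slope_gain = 1,
                             noblur_slope_gain = 1,
                             control_zero_prob = 1) {
  generator_config(slope_mean = slope, slope_sd = 0,
                   slope_range = c(min(slope, 0.88), max(slope, 2.01)),
                   intercept_mean = intercept, intercept_sd = 0,
                   noise_sd = 0, control_zero_prob = control_zero_prob,
                   right_gain = right_gain,
                   lower_slope_gain = lower_slope_gain,
                   noblur_slope_gain = noblur_slope_gain)
}

paper_offsets <- function() seq(0.14, 2.16, length.out = 6)
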