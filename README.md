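# shadowdepth

How much depth do observers infer from the offset between an object and
its cast shadow? For a frontoparallel background viewed along its normal,
the projection geometry ties the three quantities together:

    offset = depth × tan(slant)

with the shadow offset `o` and object–background depth `d` in degrees of
visual angle (dva) and the illumination *slant* σ measured from the
surface normal. An observer who sees only the offset must resolve the
slant ambiguity. `shadowdepth` implements the two standard resolutions
and everything needed to study them end to end:

* **Geometry** — `offset_from_depth()`, `depth_from_offset()`,
  `slant_from_slope()`, `penumbra_width()`, `px_to_dva()`.
* **Generic shadow-to-depth (GSD) model** — perceived depth as a fixed
  linear multiple of offset: `fit_line()` (free intercept) and the
  one-parameter `fit_through_origin()`, returning `gsd_fit` objects with
  `print`/`summary`/`coef`/`predict`/`residuals`/`plot` methods; a fitted
  slope `k` is equivalent to assuming the single slant `atan(1/k)`.
* **Bayesian observer** — a beta prior over illumination slant
  (`slant_prior()`), a flat or small-relief-favouring exponential prior
  over scene relief (`relief_prior()`), the change-of-variables
  likelihood (`shadow_likelihood()`), a trapezoid-normalized posterior
  over depth (`depth_posterior()`), the posterior-mean readout
  (`posterior_mean_depth()`), and prior estimation from judgment data
  (`fit_priors()`).
* **Stimulus renderer** — textured background and square, disc-kernel
  penumbra blur, 50% tapered shadow attenuation
  (`render_stimulus()`, `write_image()`).
* **Synthetic observers** — a calibrated generator of method-of-adjustment
  trial tables (25 participants × 300 trials by default, six offsets from
  0.14 to 2.16 dva, four diagonal directions, three blur levels,
  zero-inflated no-shadow controls): `generate_dataset()`,
  `write_trials()`/`read_trials()`.
* **Analysis** — two-stage condition means, per-participant slopes,
  control statistics, direction and blur contrasts, and
  `run_pipeline()` to chain the whole thing into a JSON-able report.

## Worked example

```r
library(shadowdepth)

trials <- generate_dataset(n_participants = 25, seed = 1)

group_fit(trials, include_control = TRUE)
#> GSD linear fit
#>   slope: 1.3473  intercept: 0.1051 dva  rmse: 0.0292 dva  n = 7

cm  <- condition_means(trials, by = "offset_dva")
gsd <- fit_through_origin(c(0, cm$offset_dva),
                          c(control_stats(trials)$mean_setting,
                            cm$mean_setting))
summary(gsd)
#> GSD fit through the origin
#>       Estimate Std. Error
#> slope   1.4145     0.0231
#> rmse: 0.0703 dva over 7 points
#> equivalent illumination slant: 35.3 degrees

fit_priors(cm$offset_dva, cm$mean_setting,
           relief_prior("exponential", scale = 1))
#> Bayesian shadow-depth observer fit
#>   slant prior: Beta(25.958, 42.052), mean slant 34.4 deg
#>   relief prior: exponential (scale = 1 dva)
#>   rmse: 0.0578 dva over 6 offsets
```

Reading: settings rise linearly with offset — depth is judged roughly 30–40%
larger than the shadow offset. The free fit over the seven condition means
(six offsets plus the offset-0 control) has slope 1.35 and a small positive
intercept; pinning the intercept to zero steepens the slope to 1.41, which
under the projection geometry is the depth an observer would recover by
assuming one generic illumination slant of ~35°. The Bayesian observer
reaches an equivalent account without committing to a single light
direction: its fitted slant prior has mean 34.4° and fits the same means
slightly better than the one-parameter line (rmse 0.058 vs 0.070 dva).

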