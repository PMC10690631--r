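# shared fixtures for the test suite

default_geometry <- scene_geometry()

# the full predictor table is cheap to build; cache one copy per test run
cached_predictors <- predictor_table()

# printed reference values for the 12 kinematic conditions: initial and
# terminal velocity (m/s) rounded to one decimal, by label and duration
reference_kinematics <- data.frame(
  label = rep(c("plus_g", "minus_g", "zero_g"), each = 4),
  duration_s = rep(c(1.1, 1.0, 0.9, 0.8), 3),
  v0 = c(2.7, 4.0, 5.5, 7.3, 13.5, 13.8, 14.3, 15.1, 8.1, 8.9, 9.9, 11.2),
  vt = c(13.5, 13.8, 14.3, 15.1, 2.7, 4.0, 5.5, 7.3, 8.1, 8.9, 9.9, 11.2)
)

# published predictor table (ms): gravity predictors at 0-600 ms engagement
# (100-ms subset) and the KS optical predictor, by label and duration
reference_predictors <- local({
  d <- rbind(
    c(551, 608, 665, 721, 777, 832, 887, 1063),
    c(541, 597, 651, 705, 758, 810, 859, 971),
    c(528, 580, 632, 682, 731, 777, 820, 879),
    c(508, 557, 605, 650, 692, 731, 765, 784),
    c(755, 802, 846, 889, 929, 967, 1001, 1100),
    c(717, 760, 800, 839, 875, 907, 936, 1000),
    c(674, 713, 749, 783, 814, 841, 864, 900),
    c(627, 661, 693, 721, 746, 768, 784, 801),
    c(1100, 1100, 1100, 1100, 1100, 1100, 1100, 1112),
    c(1000, 1000, 1000, 1000, 1000, 1000, 1000, 1012),
    c(900, 900, 900, 900, 900, 900, 900, 911),
    c(800, 800, 800, 800, 800, 800, 800, 811)
  )
  colnames(d) <- c("g_0", "g_100", "g_200", "g_300", "g_400", "g_500", "g_600",
                   "optical")
  cbind(data.frame(label = rep(c("minus_g", "zero_g", "plus_g"), each = 4),
                   duration_s = rep(c(1.1, 1.0, 0.9, 0.8), 3)),
        as.data.frame(d))
})

# reduced MCMC settings for test-scale fits: 4 chains x 250 = 1000 draws
fast_mcmc <- list(chains = 4, adapt = 300, warmup = 300, iter = 250)

fit_fast <- function(summaries, predictors = cached_predictors, ...) {
  suppressWarnings(do.call(fit_mixed,
    c(list(summaries = summaries, predictors = predictors), fast_mcmc,
      list(...))))
}

# simulate -> TE -> filter -> aggregate in one step
summaries_for <- function(params, predictors = cached_predictors) {
  aggregate_trials(filter_outliers(compute_te(
    simulate_trials(params, predictors))))
}
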