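test_that("the trial schedule is a balanced seeded permutation", {
  ct <- build_condition_table(default_geometry)
  sched <- make_schedule(20, ct, seed = 42)
  expect_equal(nrow(sched), 240)
  counts <- table(paste(sched$label, sched$duration_s))
  expect_true(all(counts == 20))
  expect_equal(sched$trial_index, 1:240)
  # single repetition: a permutation of the 12 conditions
  one <- make_schedule(1, ct, seed = 1)
  expect_setequal(paste(one$label, one$duration_s),
                  paste(ct$label, ct$duration_s))
  # determinism contract
  expect_identical(make_schedule(20, ct, seed = 42), sched)
  expect_false(identical(make_schedule(20, ct, seed = 43)$label, sched$label))
  expect_error(make_schedule(0, ct), "n_reps")
})

test_that("the noise-free generator is the identity on the predictor", {
  p <- generative_params(beta0 = 0, beta_grav = 1, sd_intercept = 0,
                         sd_slope = 0, cor_int_slope = 0, sigma_cond = 0,
                         sigma_trial = 0, n_subjects = 3, n_reps = 2, seed = 5)
  tr <- simulate_trials(p, cached_predictors)
  key <- paste(tr$label, tr$duration_s)
  pk <- paste(cached_predictors$label, cached_predictors$duration_s)
  expect_equal(tr$rt_ms, cached_predictors$g_450[match(key, pk)],
               tolerance = 1e-12)
  # aggregation of the noise-free generator recovers the latent means exactly
  sm <- aggregate_trials(compute_te(tr))
  expect_equal(sm$mean_rt,
               cached_predictors$g_450[match(paste(sm$label, sm$duration_s), pk)],
               tolerance = 1e-12)
})

test_that("the generator is bit-reproducible under a fixed seed", {
  p <- generative_params(n_subjects = 4, n_reps = 3, seed = 77)
  t1 <- simulate_trials(p, cached_predictors)
  t2 <- simulate_trials(p, cached_predictors)
  expect_identical(t1, t2)
  t3 <- simulate_trials(generative_params(n_subjects = 4, n_reps = 3, seed = 78),
                        cached_predictors)
  expect_false(identical(t1$rt_ms, t3$rt_ms))
})

test_that("timing error carries the anticipation/delay sign convention", {
  tr <- data.frame(subject_id = 1, label = "zero_g", duration_s = 1.0,
                   trial_index = 1:3, rt_ms = c(1000, 1050, 551))
  tr$duration_s[3] <- 1.1; tr$label[3] <- "minus_g"
  te <- compute_te(tr, build_condition_table(default_geometry))
  expect_equal(te$te_ms, c(0, 50, -549))
  bad <- data.frame(subject_id = 1, label = "zero_g", duration_s = 0.75,
                    trial_index = 1, rt_ms = 700)
  expect_error(compute_te(bad, build_condition_table(default_geometry)),
               "unknown condition")
})

test_that("the outlier filter flags exactly the hand-computed exceedances", {
  tr <- data.frame(subject_id = 1, label = "zero_g", duration_s = 1.0,
                   trial_index = 1:10,
                   rt_ms = 1000 + c(rep(0, 9), 100))
  tr <- compute_te(tr)
  out <- filter_outliers(tr, k = 2)
  # cell {0 x9, 100}: mean 10, sd 30 -> only the 100 exceeds 2 sd
  expect_identical(out$excluded, c(rep(FALSE, 9), TRUE))
  # constant cell: sd = 0, nothing excluded
  const <- compute_te(data.frame(subject_id = 1, label = "zero_g",
                                 duration_s = 1.0, trial_index = 1:5,
                                 rt_ms = rep(990, 5)))
  expect_false(any(filter_outliers(const)$excluded))
  expect_error(filter_outliers(const[1, ]), ">= 2 trials")
})

test_that("exclusion fraction on default synthetic data is a few percent", {
  fracs <- sapply(c(301, 302, 303), function(s) {
    tr <- filter_outliers(compute_te(
      simulate_trials(generative_params(seed = s), cached_predictors)))
    mean(tr$excluded)
  })
  # Gaussian trial noise with n = 20 per cell flags ~3.5-4.5% at k = 2
  expect_true(all(fracs > 0.025 & fracs < 0.06))
})

test_that("aggregation yields one row per subject and condition", {
  p <- generative_params(seed = 9)
  tr <- filter_outliers(compute_te(simulate_trials(p, cached_predictors)))
  sm <- aggregate_trials(tr)
  expect_equal(nrow(sm), 32 * 12)
  expect_true(all(sm$n_kept <= 20 & sm$n_kept >= 15))
  expect_equal(sum(sm$n_kept), sum(!tr$excluded))
  expect_equal(sm$mean_te, sm$mean_rt - 1000 * sm$duration_s, tolerance = 1e-9)
  # precision shrinks as trial noise vanishes
  small <- generative_params(sigma_trial = 1, seed = 9)
  sm2 <- aggregate_trials(compute_te(simulate_trials(small, cached_predictors)))
  expect_lt(mean(sm2$std_te), mean(sm$std_te))
})

test_that("generative accuracy pattern mirrors the acceleration ordering", {
  # on the latent (noise-free population) means: 1g nearly accurate, 0g
  # anticipated, -1g strongly anticipated; anticipation grows with duration
  p <- generative_params(sd_intercept = 0, sd_slope = 0, sigma_cond = 0,
                         sigma_trial = 0, n_subjects = 1, n_reps = 1, seed = 1)
  tr <- compute_te(simulate_trials(p, cached_predictors))
  te <- tapply(tr$te_ms, list(tr$label, tr$duration_s), mean)
  for (T in colnames(te)) {
    expect_lt(abs(te["plus_g", T]), abs(te["zero_g", T]))
    expect_lt(abs(te["zero_g", T]), abs(te["minus_g", T]))
  }
  for (lab in c("minus_g", "zero_g"))
    expect_true(all(diff(abs(te[lab, order(as.numeric(colnames(te)))])) > 0))
})

test_that("subject-level intercept spread matches the generative variance", {
  p <- generative_params(seed = 21)
  sm <- summaries_for(p)
  pk <- paste(cached_predictors$label, cached_predictors$duration_s)
  P <- cached_predictors$g_450[match(paste(sm$label, sm$duration_s), pk)]
  ints <- sapply(split(data.frame(y = sm$mean_rt, P = P), sm$subject_id),
                 function(d) coef(lm(y ~ P, d))[1])
  ratio <- var(ints) / 68.08^2
  # chi-square sampling band for a variance estimated from 32 subjects
  expect_gt(ratio, 0.45)
  expect_lt(ratio, 2.2)
})

test_that("trials and summaries round-trip through CSV", {
  p <- generative_params(n_subjects = 3, n_reps = 2, seed = 4)
  tr <- filter_outliers(compute_te(simulate_trials(p, cached_predictors)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back$rt_ms, tr$rt_ms)
  expect_identical(back$excluded, tr$excluded)
  sm <- aggregate_trials(tr)
  write_summaries(sm, path)
  expect_equal(read_summaries(path)$mean_rt, sm$mean_rt)
  writeLines("a,b\n1,2", path)
  expect_error(read_trials(path), "missing columns")
})
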