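# reproducible pointwise log-likelihood matrix; reference ELPD and Pareto-k
# values for it were computed with an independent PSIS implementation
# (arviz.stats.psislw) and frozen below
frozen_loglik <- function() {
  withr::with_seed(20240601L, {
    S <- 2000; N <- 25
    y <- rnorm(N)
    mu <- matrix(rnorm(S * N, 0, 0.6), S, N)
    sig <- matrix(exp(rnorm(S * N, 0, 0.15)), S, N)
    dnorm(matrix(y, S, N, byrow = TRUE), mu, sig, log = TRUE)
  })
}

test_that("PSIS-LOO matches the frozen independent reference", {
  ll <- frozen_loglik()
  r <- psis_loo(ll)
  expect_equal(r$elpd_loo, -55.28988249638928, tolerance = 1e-10)
  expect_equal(r$se, 8.303760520807598, tolerance = 1e-10)
  expect_equal(max(r$pareto_k), 1.6928803494445857, tolerance = 1e-10)
  expect_equal(r$pointwise[1:5],
               c(-1.2768709202345545, -8.879571741399078, -1.1946075735857298,
                 -1.295665620398855, -1.3595276303803858), tolerance = 1e-10)
})

test_that("the generalized Pareto fit recovers a known tail shape", {
  withr::with_seed(42, {
    for (xi in c(0.2, 0.5)) {
      x <- 2 / xi * ((1 - runif(4000))^(-xi) - 1)  # GPD(xi, sigma = 2) draws
      fit <- gravicept:::.gpd_fit(x)
      expect_equal(fit$k, xi, tolerance = 0.1)
      expect_equal(fit$sigma, 2, tolerance = 0.25)
    }
  })
})

test_that("comparing a model with itself gives a null LOO difference", {
  ll <- frozen_loglik()
  fake <- structure(list(loglik = ll, loo = psis_loo(ll)), class = "mixed_fit")
  cmp <- suppressWarnings(compare_loo(fake, fake))
  expect_equal(cmp$elpd_diff, 0)
  expect_equal(cmp$se_diff, 0)
  expect_false(cmp$significant)
})

test_that("rank-normalized diagnostics behave on iid chains", {
  withr::with_seed(8, {
    x <- matrix(rnorm(4000), 1000, 4)
    expect_lt(gravicept:::.rhat(x), 1.01)
    expect_gt(gravicept:::.ess_bulk(x), 2000)
    expect_gt(gravicept:::.ess_tail(x), 1000)
    # a drifting chain is flagged
    bad <- x; bad[, 1] <- bad[, 1] + seq(0, 8, length.out = 1000)
    expect_gt(gravicept:::.rhat(bad), 1.05)
  })
})

test_that("near-noise-free data recover slope one and intercept zero", {
  # tiny but identified between-subject spread: with all variances exactly
  # zero the subject effects coincide and the correlation posterior
  # degenerates onto the rho = +/-1 ridge
  p <- generative_params(beta0 = 0, beta_grav = 1, sd_intercept = 5,
                         sd_slope = 0.01, cor_int_slope = 0,
                         sigma_cond = 2, sigma_trial = 2,
                         n_subjects = 16, n_reps = 4, seed = 51)
  sm <- summaries_for(p)
  # low-variance regimes need a longer warmup to leave the correlation ridge
  f <- suppressWarnings(fit_mixed(sm, cached_predictors, gravity_col = "g_450",
                                  chains = 4, adapt = 1000, warmup = 1500,
                                  iter = 500, seed = 51))
  slope <- f$summary[f$summary$term == "slope_g_450", ]
  int <- f$summary[f$summary$term == "intercept", ]
  expect_lt(abs(slope$mean - 1), 0.01)
  expect_lt(abs(int$mean), 3 * int$sd + 5)
  expect_gt(f$bayes_r2$mean, 0.999)
})

test_that("pure-noise data yield a near-zero Bayesian R-squared", {
  sm <- summaries_for(generative_params(seed = 61))
  sm$mean_rt <- withr::with_seed(61, rnorm(nrow(sm), 800, 30))
  f <- fit_fast(sm, gravity_col = "g_450", seed = 61)
  expect_lt(f$bayes_r2$mean, 0.25)
  slope <- f$summary[f$summary$term == "slope_g_450", ]
  expect_lt(abs(slope$mean), 3 * slope$sd + 0.05)
})

test_that("rescaling the response rescales the location parameters", {
  p <- generative_params(n_subjects = 16, seed = 71)
  sm <- summaries_for(p)
  f1 <- fit_fast(sm, gravity_col = "g_450", seed = 71)
  sm2 <- sm; sm2$mean_rt <- 2 * sm2$mean_rt
  f2 <- fit_fast(sm2, gravity_col = "g_450", seed = 71)
  get <- function(f, term, col = "mean") f$summary[f$summary$term == term, col]
  expect_equal(get(f2, "slope_g_450") / get(f1, "slope_g_450"), 2,
               tolerance = 0.05)
  expect_equal(get(f2, "sigma") / get(f1, "sigma"), 2, tolerance = 0.15)
  expect_equal(get(f2, "intercept"), 2 * get(f1, "intercept"),
               tolerance = 3 * (get(f2, "intercept", "sd") +
                                2 * get(f1, "intercept", "sd")))
})

test_that("a well-specified fit predicts the observed distribution", {
  sm <- summaries_for(generative_params(seed = 81))
  f <- fit_fast(sm, gravity_col = "g_450", seed = 81)
  # observed-vs-predicted clusters on the unit-slope line
  b <- coef(lm(sm$mean_rt ~ predicted_means(f)))[2]
  expect_gt(b, 0.9); expect_lt(b, 1.1)
  # posterior-predictive envelope covers the observed density
  yrep <- posterior_predict(f, ndraws = 200, seed = 81)
  grid <- seq(min(sm$mean_rt), max(sm$mean_rt), length.out = 64)
  dens <- function(y) density(y, from = grid[1], to = grid[64], n = 64)$y
  obs <- dens(sm$mean_rt)
  env <- apply(yrep, 1, dens)
  inside <- obs >= apply(env, 1, min) & obs <= apply(env, 1, max)
  expect_gt(mean(inside), 0.95)
  # nesting: adding a predictor cannot reduce explained variance materially
  fa <- fit_fast(sm, gravity_col = "g_450", extra_cols = "optical", seed = 81)
  expect_gt(fa$bayes_r2$mean, f$bayes_r2$mean - 0.01)
})

test_that("fit_mixed validates predictors and data consistency", {
  sm <- summaries_for(generative_params(n_subjects = 4, seed = 2))
  expect_error(fit_mixed(sm, cached_predictors, gravity_col = "g_425"),
               "lacks columns")
  expect_error(scan_engagement_times(sm, cached_predictors,
                                     grid_ms = c(425)), "lacks grid")
  sm_bad <- sm; sm_bad$duration_s[1] <- 0.75
  expect_error(fit_mixed(sm_bad, cached_predictors), "absent from the predictor")
})
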