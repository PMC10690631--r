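#' Priors for the Bayesian mixed regression
#'
#' The fixed slope of each arrival-time predictor gets a Normal(0, `slope_sd`)
#' prior — sensible on the raw millisecond scale because the slope is a
#' dimensionless ms-per-ms gain expected near 1. The intercept and the
#' random-effect / residual SDs get weakly informative Student-t priors whose
#' center and scale default to data-dependent values (median and 2.5 times
#' the MAD of the response), and the random intercept-slope correlation is
#' uniform on [-1, 1] (the LKJ(1) prior for a 2 x 2 correlation matrix).
#'
#' @param slope_sd SD of the normal prior on fixed predictor slopes.
#' @param intercept_df,sd_df Degrees of freedom of the Student-t priors.
#' @param intercept_center,intercept_scale,sd_scale Optional numeric
#'   overrides of the data-dependent defaults.
#' @return An object of class `mixed_priors`.
#' @export
mixed_priors <- function(slope_sd = 1, intercept_df = 3, sd_df = 3,
                         intercept_center = NULL, intercept_scale = NULL,
                         sd_scale = NULL) {
  structure(list(slope_sd = slope_sd, intercept_df = intercept_df,
                 sd_df = sd_df, intercept_center = intercept_center,
                 intercept_scale = intercept_scale, sd_scale = sd_scale),
            class = "mixed_priors")
}

# resolve data-dependent prior locations/scales, brms-style
.resolve_priors <- function(priors, y) {
  sc <- max(stats::mad(y), 2.5)
  list(slope_sd = priors$slope_sd,
       intercept_df = priors$intercept_df,
       sd_df = priors$sd_df,
       intercept_center = priors$intercept_center %||% stats::median(y),
       intercept_scale = priors$intercept_scale %||% (2.5 * sc),
       sd_scale = priors$sd_scale %||% (2.5 * sc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# JAGS model for a hierarchically centered random intercept + slope model,
# optionally with extra fixed-effect-only predictors (columns of Z)
.jags_model_string <- function(n_extra) {
  extra_mu <- if (n_extra > 0) " + inprod(Z[n,], beta_x)" else ""
  extra_prior <- if (n_extra > 0)
    "  for (k in 1:K) { beta_x[k] ~ dnorm(0, prec_slope) }\n" else ""
  paste0("model {
  for (n in 1:N) {
    mu[n] <- b[subj[n],1] + b[subj[n],2] * x[n]", extra_mu, "
    y[n] ~ dnorm(mu[n], tau_y)
    loglik[n] <- logdensity.norm(y[n], mu[n], tau_y)
  }
  # subject effects centered on the fixed effects (hierarchical centering,
  # which mixes far better than zero-centered effects under Gibbs sampling)
  for (j in 1:J) { b[j,1:2] ~ dmnorm(beta[1:2], Omega) }
  Omega <- inverse(Sigma)
  Sigma[1,1] <- pow(sd_intercept, 2)
  Sigma[2,2] <- pow(sd_slope, 2)
  Sigma[1,2] <- rho * sd_intercept * sd_slope
  Sigma[2,1] <- Sigma[1,2]
  rho ~ dunif(-1, 1)
  sd_intercept ~ dt(0, prec_sd, sd_df) T(0,)
  sd_slope ~ dt(0, prec_sd, sd_df) T(0,)
  sigma ~ dt(0, prec_sd, sd_df) T(0,)
  tau_y <- pow(sigma, -2)
  beta[1] ~ dt(int_center, prec_int, int_df)
  beta[2] ~ dnorm(0, prec_slope)
", extra_prior, "}\n")
}

# ---- MCMC diagnostics (rank-normalized split chains) ----

.rank_normalize <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (length(x) + 1 / 4))
}

# split each chain in half; x is an iterations x chains matrix
.split_chains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE], x[(n - h + 1):n, , drop = FALSE])
}

.rhat <- function(x) {
  z <- matrix(.rank_normalize(as.vector(x)), nrow(x), ncol(x))
  z <- .split_chains(z)
  m <- ncol(z); n <- nrow(z)
  mu <- colMeans(z)
  B <- n * stats::var(mu)
  W <- mean(apply(z, 2, stats::var))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess_of <- function(x) {
  z <- .split_chains(x)
  ml <- coda::as.mcmc.list(lapply(seq_len(ncol(z)), function(j) coda::mcmc(z[, j])))
  as.numeric(coda::effectiveSize(ml))
}

.ess_bulk <- function(x) {
  z <- matrix(.rank_normalize(as.vector(x)), nrow(x), ncol(x))
  .ess_of(z)
}

.ess_tail <- function(x) {
  q <- stats::quantile(as.vector(x), c(0.05, 0.95), names = FALSE)
  e1 <- .ess_of(matrix(.rank_normalize(as.vector(x <= q[1])), nrow(x), ncol(x)))
  e2 <- .ess_of(matrix(.rank_normalize(as.vector(x <= q[2])), nrow(x), ncol(x)))
  min(e1, e2)
}

# ---- PSIS-LOO ----

.log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# profile-likelihood generalized Pareto fit (Zhang & Stephens 2009) with the
# usual weak prior regularization of the shape towards 0.5
.gpd_fit <- function(x) {
  n <- length(x)
  x <- sort(x)
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  prof <- vapply(theta, function(th) {
    k <- mean(log1p(-th * x))
    n * (log(-th / k) - k - 1)
  }, numeric(1))
  w <- 1 / vapply(jj, function(j) sum(exp(prof - prof[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  k <- (n * k + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

.gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth one vector of log importance ratios; returns unnormalized
# smoothed log weights and the shape diagnostic
.psis_smooth <- function(log_ratios) {
  S <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5) return(list(lw = lw, k = Inf))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  if (max(exceed) <= 0) return(list(lw = lw, k = -Inf))
  fit <- .gpd_fit(exceed)
  if (is.finite(fit$k)) {
    p <- (seq_len(M) - 0.5) / M
    smoothed <- log(vapply(p, .gpd_quantile, numeric(1),
                           k = fit$k, sigma = fit$sigma) + exp(cutoff))
    lw[tail_ids] <- pmin(smoothed, 0)  # cap at the raw maximum
  }
  list(lw = lw, k = fit$k)
}

#' Pareto-smoothed importance-sampling LOO cross-validation
#'
#' Estimates the expected log pointwise predictive density (ELPD) under
#' leave-one-out cross-validation from a matrix of pointwise posterior
#' log-likelihoods, smoothing the tail of each observation's importance
#' weights with a generalized Pareto fit. The fitted Pareto shape `k` per
#' observation diagnoses the reliability of the estimate (values above 0.7
#' are flagged).
#'
#' @param loglik Draws-by-observations matrix of log-likelihood values.
#' @return An object of class `psis_loo`: `elpd_loo`, `se`, `pointwise`
#'   (per-observation ELPD), `pareto_k`, `n_high_k`.
#' @export
psis_loo <- function(loglik) {
  stopifnot(is.matrix(loglik), nrow(loglik) > 1)
  N <- ncol(loglik)
  pointwise <- numeric(N)
  pareto_k <- numeric(N)
  for (i in seq_len(N)) {
    sm <- .psis_smooth(-loglik[, i])
    lw <- sm$lw - .log_sum_exp(sm$lw)
    pointwise[i] <- .log_sum_exp(lw + loglik[, i])
    pareto_k[i] <- sm$k
  }
  structure(list(elpd_loo = sum(pointwise),
                 se = sqrt(N * stats::var(pointwise)),
                 pointwise = pointwise,
                 pareto_k = pareto_k,
                 n_high_k = sum(pareto_k > 0.7)),
            class = "psis_loo")
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd = %.1f (SE %.1f), %d/%d observations with Pareto k > 0.7\n",
              x$elpd_loo, x$se, x$n_high_k, length(x$pointwise)))
  invisible(x)
}

# ---- model fitting ----

#' Fit the Bayesian linear mixed regression of mean RT on a predictor
#'
#' Hierarchical linear model of per-subject, per-condition mean response
#' times on an arrival-time predictor: fixed intercept and slope, correlated
#' random intercept and slope per subject, Gaussian residual. Optional extra
#' predictors (e.g. the KS optical predictor) enter as fixed effects only.
#' The posterior is sampled by Gibbs sampling in JAGS with `chains` chains;
#' defaults give 4 x 1000 = 4000 post-warmup draws.
#'
#' @param summaries Subject-by-condition summary table with `label`,
#'   `duration_s` and `mean_rt` (see [aggregate_trials()]).
#' @param predictors Predictor table from [predictor_table()].
#' @param gravity_col Name of the predictor column receiving fixed + random
#'   slopes (e.g. `"g_450"`).
#' @param extra_cols Names of predictor columns entering as fixed effects
#'   only (e.g. `"optical"`).
#' @param priors A [mixed_priors()] object.
#' @param chains,warmup,iter,adapt MCMC settings: number of chains, burn-in
#'   iterations, retained iterations per chain, and adaptation steps.
#' @param seed Integer seed for the samplers.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `mixed_fit`: `summary` (posterior mean, sd,
#'   Rhat, bulk/tail ESS per parameter), `draws`, `mu_draws`, `loglik`,
#'   `bayes_r2`, `sigma2`, `loo`, `converged`, `data`.
#' @export
fit_mixed <- function(summaries, predictors = predictor_table(),
                      gravity_col = "g_450", extra_cols = character(),
                      priors = mixed_priors(),
                      chains = 4, warmup = 1000, iter = 1000, adapt = 1000,
                      seed = 1L, quiet = TRUE) {
  need <- c(gravity_col, extra_cols)
  if (!all(need %in% names(predictors)))
    stop("predictor table lacks columns: ",
         paste(setdiff(need, names(predictors)), collapse = ", "))
  d <- merge(summaries, predictors[, c("label", "duration_s", need)],
             by = c("label", "duration_s"), sort = FALSE)
  if (nrow(d) != nrow(summaries))
    stop("summaries contain conditions absent from the predictor table")
  d <- d[order(d$subject_id, match(d$label, .motion_labels), d$duration_s), ]
  subjects <- sort(unique(d$subject_id))
  y <- d$mean_rt
  pr <- .resolve_priors(priors, y)
  K <- length(extra_cols)
  data_list <- list(N = nrow(d), J = length(subjects), y = y,
                    x = d[[gravity_col]],
                    subj = match(d$subject_id, subjects),
                    prec_sd = 1 / pr$sd_scale^2, sd_df = pr$sd_df,
                    int_center = pr$intercept_center,
                    prec_int = 1 / pr$intercept_scale^2, int_df = pr$intercept_df,
                    prec_slope = 1 / pr$slope_sd^2)
  if (K > 0) {
    data_list$Z <- as.matrix(d[, extra_cols, drop = FALSE])
    data_list$K <- K
  }
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) * 97L + ch * 1009L) %% 2147483647L + 1L)
  })
  monitors <- c("beta", if (K > 0) "beta_x", "sd_intercept", "sd_slope",
                "rho", "sigma", "mu", "loglik")
  run <- function() {
    jm <- rjags::jags.model(textConnection(.jags_model_string(K)),
                            data = data_list, inits = inits,
                            n.chains = chains, n.adapt = adapt, quiet = quiet)
    update(jm, warmup, progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = iter, progress.bar = "none")
  }
  samp <- if (quiet) suppressWarnings(run()) else run()

  vn <- coda::varnames(samp)
  # JAGS drops the index on monitored vectors of length 1
  extra_pars <- if (K == 1) "beta_x" else if (K > 1)
    paste0("beta_x[", seq_len(K), "]") else character()
  scalar_pars <- c("beta[1]", "beta[2]", extra_pars,
                   "sd_intercept", "sd_slope", "rho", "sigma")
  term_names <- c("intercept", paste0("slope_", gravity_col),
                  if (K > 0) paste0("slope_", extra_cols),
                  "sd_intercept", "sd_slope", "cor_intercept_slope", "sigma")
  # iterations x chains matrix per parameter
  as_ic <- function(par) sapply(samp, function(ch) as.matrix(ch)[, par])
  summ <- do.call(rbind, lapply(seq_along(scalar_pars), function(i) {
    m <- as_ic(scalar_pars[i])
    data.frame(term = term_names[i], mean = mean(m), sd = stats::sd(as.vector(m)),
               rhat = .rhat(m), ess_bulk = .ess_bulk(m), ess_tail = .ess_tail(m))
  }))
  rownames(summ) <- NULL

  pooled <- do.call(rbind, lapply(samp, as.matrix))
  mu_draws <- pooled[, grep("^mu\\[", vn, value = TRUE), drop = FALSE]
  loglik <- pooled[, grep("^loglik\\[", vn, value = TRUE), drop = FALSE]
  # restore observation order (JAGS sorts node names lexicographically)
  ob <- order(as.integer(sub("^mu\\[(\\d+)\\]$", "\\1", colnames(mu_draws))))
  mu_draws <- mu_draws[, ob, drop = FALSE]
  ob <- order(as.integer(sub("^loglik\\[(\\d+)\\]$", "\\1", colnames(loglik))))
  loglik <- loglik[, ob, drop = FALSE]
  sigma_draws <- pooled[, "sigma"]

  r2_draws <- apply(mu_draws, 1, stats::var)
  r2_draws <- r2_draws / (r2_draws + sigma_draws^2)
  converged <- all(is.finite(summ$rhat)) && all(summ$rhat < 1.01)
  if (!converged)
    warning("some Rhat >= 1.01; inspect the summary and consider longer chains")
  structure(list(
    summary = summ,
    draws = pooled[, scalar_pars, drop = FALSE],
    mu_draws = mu_draws,
    loglik = loglik,
    data = d,
    gravity_col = gravity_col,
    extra_cols = extra_cols,
    n_draws = nrow(pooled),
    bayes_r2 = list(mean = mean(r2_draws),
                    lower = unname(stats::quantile(r2_draws, 0.025)),
                    upper = unname(stats::quantile(r2_draws, 0.975)),
                    draws = r2_draws),
    sigma2 = mean(sigma_draws^2),
    loo = psis_loo(loglik),
    converged = converged
  ), class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("Bayesian mixed regression of mean RT on %s%s (%d draws%s)\n",
              x$gravity_col,
              if (length(x$extra_cols)) paste0(" + ", paste(x$extra_cols, collapse = " + ")) else "",
              x$n_draws,
              if (x$converged) "" else "; NOT converged"))
  s <- x$summary
  s[-1] <- lapply(s[-1], function(v) round(v, 3))
  print(s, row.names = FALSE)
  cat(sprintf("Bayesian R2 = %.3f [%.3f, %.3f]; sigma^2 = %.1f ms^2; elpd_loo = %.1f\n",
              x$bayes_r2$mean, x$bayes_r2$lower, x$bayes_r2$upper,
              x$sigma2, x$loo$elpd_loo))
  invisible(x)
}

#' Posterior-draw Bayesian R-squared
#'
#' Per posterior draw, the ratio of the variance of the linear predictor over
#' the observations to that variance plus the draw's residual variance;
#' summarizes how much of the data variation the model accounts for.
#'
#' @param fit A [fit_mixed()] result.
#' @return List with `mean`, `lower`, `upper` (95% interval) and the
#'   per-draw values.
#' @export
bayes_r2 <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  fit$bayes_r2
}

#' Posterior mean predictions per observation
#'
#' @param fit A [fit_mixed()] result.
#' @return Numeric vector aligned with `fit$data`.
#' @export
predicted_means <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  colMeans(fit$mu_draws)
}

#' Posterior-predictive replicated datasets
#'
#' @param fit A [fit_mixed()] result.
#' @param ndraws Number of replicated datasets (rows); defaults to all draws.
#' @param seed Optional seed for the predictive noise.
#' @return A `ndraws` x observations matrix of replicated responses.
#' @export
posterior_predict <- function(fit, ndraws = NULL, seed = NULL) {
  stopifnot(inherits(fit, "mixed_fit"))
  S <- nrow(fit$mu_draws)
  take <- if (is.null(ndraws)) seq_len(S) else
    round(seq(1, S, length.out = min(ndraws, S)))
  sim <- function() {
    noise <- stats::rnorm(length(take) * ncol(fit$mu_draws), 0,
                          fit$draws[take, "sigma"])
    fit$mu_draws[take, , drop = FALSE] +
      matrix(noise, length(take), ncol(fit$mu_draws))
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Scan engagement times of the gravity prior
#'
#' Fits one Bayesian mixed regression per engagement time on the grid and
#' profiles the Bayesian R-squared and expected error variance across them;
#' the best engagement time is the one maximizing R-squared (equivalently,
#' in practice, minimizing the error variance).
#'
#' @param summaries Subject-by-condition summary table.
#' @param predictors Predictor table containing a `g_<ms>` column for every
#'   grid point.
#' @param grid_ms Engagement times to scan (ms).
#' @param keep_best Retain the full fit of the best model as `$best_fit`.
#' @param ... Passed to [fit_mixed()] (chains, iterations, seed, priors...).
#' @return An object of class `engagement_scan`: `profile` (data frame with
#'   `engagement_ms`, `bayes_r2`, `sigma2`, `elpd_loo`, `converged`),
#'   `best_time` (argmax R2), `best_time_sigma2` (argmin error variance),
#'   and optionally `best_fit`.
#' @export
scan_engagement_times <- function(summaries, predictors = predictor_table(),
                                  grid_ms = seq(0, 600, by = 50),
                                  keep_best = TRUE, ...) {
  cols <- paste0("g_", grid_ms)
  missing_cols <- setdiff(cols, names(predictors))
  if (length(missing_cols))
    stop("predictor table lacks grid columns: ", paste(missing_cols, collapse = ", "))
  fits <- vector("list", length(grid_ms))
  rows <- vector("list", length(grid_ms))
  for (i in seq_along(grid_ms)) {
    f <- fit_mixed(summaries, predictors, gravity_col = cols[i], ...)
    rows[[i]] <- data.frame(engagement_ms = grid_ms[i],
                            bayes_r2 = f$bayes_r2$mean,
                            sigma2 = f$sigma2,
                            elpd_loo = f$loo$elpd_loo,
                            converged = f$converged)
    fits[[i]] <- if (keep_best) f else NULL
  }
  profile <- do.call(rbind, rows)
  best_i <- which.max(profile$bayes_r2)
  out <- list(profile = profile,
              best_time = grid_ms[best_i],
              best_time_sigma2 = grid_ms[which.min(profile$sigma2)])
  if (keep_best) out$best_fit <- fits[[best_i]]
  structure(out, class = "engagement_scan")
}

#' @export
print.engagement_scan <- function(x, ...) {
  cat("Engagement-time scan of the gravity prior\n")
  p <- x$profile
  p$bayes_r2 <- round(p$bayes_r2, 4)
  p$sigma2 <- round(p$sigma2, 1)
  p$elpd_loo <- round(p$elpd_loo, 1)
  print(p, row.names = FALSE)
  cat(sprintf("best engagement time: %d ms (max R2), %d ms (min sigma^2)\n",
              x$best_time, x$best_time_sigma2))
  invisible(x)
}

#' Compare two mixed fits by PSIS-LOO
#'
#' Computes the ELPD difference (augmented minus base) and its standard
#' error from the paired pointwise ELPD values. The augmented model is
#' declared a significant improvement when the difference exceeds 4 and its
#' own standard error.
#'
#' @param fit_base,fit_augmented Two [fit_mixed()] results on identical data
#'   rows.
#' @return A list: `elpd_diff`, `se_diff`, `significant`, and each model's
#'   `elpd_loo`.
#' @export
compare_loo <- function(fit_base, fit_augmented) {
  stopifnot(inherits(fit_base, "mixed_fit"), inherits(fit_augmented, "mixed_fit"))
  if (ncol(fit_base$loglik) != ncol(fit_augmented$loglik))
    stop("fits must be on identical data rows")
  if (fit_base$loo$n_high_k + fit_augmented$loo$n_high_k > 0)
    warning("some Pareto k > 0.7; LOO estimates may be unstable")
  dp <- fit_augmented$loo$pointwise - fit_base$loo$pointwise
  elpd_diff <- sum(dp)
  se_diff <- sqrt(length(dp) * stats::var(dp))
  list(elpd_diff = elpd_diff,
       se_diff = se_diff,
       significant = (elpd_diff > 4) && (elpd_diff > se_diff),
       elpd_base = fit_base$loo$elpd_loo,
       elpd_augmented = fit_augmented$loo$elpd_loo)
}
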