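#' Parameters of the generative model for interception responses
#'
#' Describes a population of subjects whose per-condition mean response times
#' follow a linear mixed model on an arrival-time predictor: subject i has a
#' random intercept and slope drawn from a correlated bivariate normal, the
#' latent mean for condition j is
#' `beta0 + b0_i + (beta_grav + b1_i) * P_j + cond_noise`, and individual
#' trials scatter around it with independent Gaussian noise. The predictor
#' `P_j` is a mixture of the gravity predictor at `engagement_ms` and the KS
#' optical predictor, with weight `w_optical` on the latter.
#'
#' Defaults describe a population whose responses track the gravity predictor
#' engaged 450 ms after motion onset almost one-to-one (slope 0.99), with
#' ~68 ms of between-subject intercept spread, and no optical contribution.
#'
#' @param beta0 Fixed intercept (ms).
#' @param beta_grav Fixed slope on the predictor (dimensionless, ms per ms).
#' @param sd_intercept Between-subject SD of the intercept (ms).
#' @param sd_slope Between-subject SD of the slope.
#' @param cor_int_slope Correlation between random intercept and slope.
#' @param sigma_cond Condition-level residual SD (ms): subject-by-condition
#'   lack of fit around the linear model.
#' @param sigma_trial Trial-level response noise SD (ms).
#' @param w_optical Mixture weight on the optical predictor, in `[0, 1]`.
#' @param engagement_ms Engagement time of the gravity predictor used as the
#'   generative truth (ms; must be on the predictor grid).
#' @param n_subjects Number of simulated subjects.
#' @param n_reps Trial repetitions per condition and subject.
#' @param seed Integer seed making the whole simulation reproducible.
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(beta0 = -8.8,
                              beta_grav = 0.99,
                              sd_intercept = 68.08,
                              sd_slope = 0.02,
                              cor_int_slope = -0.5,
                              sigma_cond = 20,
                              sigma_trial = 60,
                              w_optical = 0,
                              engagement_ms = 450,
                              n_subjects = 32,
                              n_reps = 20,
                              seed = 1L) {
  p <- list(beta0 = beta0, beta_grav = beta_grav, sd_intercept = sd_intercept,
            sd_slope = sd_slope, cor_int_slope = cor_int_slope,
            sigma_cond = sigma_cond, sigma_trial = sigma_trial,
            w_optical = w_optical, engagement_ms = engagement_ms,
            n_subjects = as.integer(n_subjects), n_reps = as.integer(n_reps),
            seed = as.integer(seed))
  if (any(c(p$sd_intercept, p$sd_slope, p$sigma_cond, p$sigma_trial) < 0))
    stop("standard deviations must be non-negative")
  if (abs(p$cor_int_slope) > 1) stop("cor_int_slope must lie in [-1, 1]")
  if (p$w_optical < 0 || p$w_optical > 1) stop("w_optical must lie in [0, 1]")
  if (p$n_subjects < 1 || p$n_reps < 1) stop("n_subjects and n_reps must be >= 1")
  structure(p, class = "generative_params")
}

#' Pseudorandom trial schedule
#'
#' Produces a seeded uniform permutation of `n_reps` copies of each
#' condition, mirroring an experimental session in which every condition is
#' presented the same number of times in shuffled order.
#'
#' @param n_reps Repetitions per condition.
#' @param conditions A condition table from [build_condition_table()].
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return A data frame with `trial_index`, `label`, `duration_s`.
#' @export
make_schedule <- function(n_reps, conditions, seed = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  idx <- rep(seq_len(nrow(conditions)), times = n_reps)
  perm <- if (is.null(seed)) sample(idx) else
    withr::with_seed(seed, sample(idx))
  data.frame(trial_index = seq_along(perm),
             label = conditions$label[perm],
             duration_s = conditions$duration_s[perm])
}

# latent per-subject per-condition means implied by the generative model;
# returns an n_subjects x n_conditions matrix (no condition-level noise)
.latent_means <- function(params, pred_values, subj_effects) {
  (params$beta0 + subj_effects[, 1]) +
    outer(params$beta_grav + subj_effects[, 2], pred_values)
}

#' Simulate trial-level interception responses
#'
#' Draws per-subject random effects, builds the latent subject-by-condition
#' mean response times from the predictor mixture, and scatters `n_reps`
#' trials per cell with trial-level noise. Each subject receives an
#' independently shuffled schedule. Fully reproducible from `params$seed`.
#'
#' @param params A [generative_params()] object.
#' @param predictors A predictor table from [predictor_table()].
#' @return A data frame of trial records: `subject_id`, `label`,
#'   `duration_s`, `trial_index`, `rt_ms`, plus attribute `"latent_means"`
#'   (the noise-free subject-by-condition means) and `"subject_effects"`.
#' @export
simulate_trials <- function(params, predictors = predictor_table()) {
  stopifnot(inherits(params, "generative_params"))
  gcol <- paste0("g_", params$engagement_ms)
  if (!gcol %in% names(predictors))
    stop("engagement_ms = ", params$engagement_ms,
         " is not on the predictor grid (no column ", gcol, ")")
  P <- (1 - params$w_optical) * predictors[[gcol]] +
    params$w_optical * predictors$optical
  n_cond <- nrow(predictors)
  Sigma <- matrix(c(params$sd_intercept^2,
                    rep(params$cor_int_slope * params$sd_intercept * params$sd_slope, 2),
                    params$sd_slope^2), 2, 2)
  if (any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
    stop("random-effect covariance is not positive semi-definite")
  withr::with_seed(params$seed, {
    u <- MASS::mvrnorm(params$n_subjects, c(0, 0), Sigma)
    u <- matrix(u, ncol = 2)
    latent <- .latent_means(params, P, u)
    cond_eps <- matrix(stats::rnorm(params$n_subjects * n_cond, 0, params$sigma_cond),
                       params$n_subjects, n_cond)
    cell_mean <- latent + cond_eps
    trials <- do.call(rbind, lapply(seq_len(params$n_subjects), function(i) {
      sched <- make_schedule(params$n_reps, predictors[, c("label", "duration_s")])
      ci <- match(paste(sched$label, sched$duration_s),
                  paste(predictors$label, predictors$duration_s))
      data.frame(subject_id = i,
                 label = sched$label,
                 duration_s = sched$duration_s,
                 trial_index = sched$trial_index,
                 rt_ms = cell_mean[i, ci] +
                   stats::rnorm(nrow(sched), 0, params$sigma_trial))
    }))
  })
  rownames(trials) <- NULL
  attr(trials, "latent_means") <- latent
  attr(trials, "subject_effects") <- u
  trials
}

#' Timing error of each trial
#'
#' The timing error (TE) is the button-press response time minus the true
#' arrival time of the ball at the ring: negative values are anticipated
#' responses, positive values delayed ones.
#'
#' @param trials A trial data frame with `rt_ms` and `duration_s`.
#' @param conditions Optional condition table used to validate the trials'
#'   condition keys.
#' @return The trials with a `te_ms` column added.
#' @export
compute_te <- function(trials, conditions = NULL) {
  if (!is.null(conditions)) {
    known <- paste(conditions$label, conditions$duration_s)
    bad <- !paste(trials$label, trials$duration_s) %in% known
    if (any(bad)) stop("unknown condition key in trials: ",
                       paste(unique(paste(trials$label[bad], trials$duration_s[bad])),
                             collapse = ", "))
  }
  trials$te_ms <- trials$rt_ms - 1000 * trials$duration_s
  trials
}

#' Flag outlying trials per subject and condition
#'
#' Single-pass filter: within each subject-by-condition cell, trials whose
#' timing error lies more than `k` sample standard deviations (n-1
#' denominator) from the cell mean are flagged as excluded.
#'
#' @param trials A trial data frame with `te_ms` (see [compute_te()]).
#' @param k Exclusion threshold in standard deviations.
#' @return The trials with a logical `excluded` column.
#' @export
filter_outliers <- function(trials, k = 2) {
  if (!"te_ms" %in% names(trials)) stop("trials must carry te_ms; run compute_te() first")
  cell <- interaction(trials$subject_id, trials$label, trials$duration_s, drop = TRUE)
  if (any(table(cell) < 2)) stop("every subject-by-condition cell needs >= 2 trials")
  mu <- ave(trials$te_ms, cell, FUN = mean)
  sd_ <- ave(trials$te_ms, cell, FUN = stats::sd)
  trials$excluded <- abs(trials$te_ms - mu) > k * sd_
  trials
}

#' Aggregate kept trials into subject-by-condition summaries
#'
#' @param trials A filtered trial data frame (see [filter_outliers()]); if no
#'   `excluded` column is present all trials are kept.
#' @return A data frame with one row per subject and condition: `subject_id`,
#'   `label`, `duration_s`, `mean_rt`, `mean_te`, `std_te`, `n_kept`.
#' @export
aggregate_trials <- function(trials) {
  if (!"te_ms" %in% names(trials)) trials <- compute_te(trials)
  if (!"excluded" %in% names(trials)) trials$excluded <- FALSE
  kept <- trials[!trials$excluded, ]
  key <- interaction(kept$subject_id, kept$label, kept$duration_s, drop = FALSE)
  if (any(tabulate(key) == 0) || anyNA(key))
    stop("a subject-by-condition cell is empty after filtering")
  agg <- do.call(rbind, lapply(split(kept, key, drop = TRUE), function(d) {
    data.frame(subject_id = d$subject_id[1], label = d$label[1],
               duration_s = d$duration_s[1],
               mean_rt = mean(d$rt_ms), mean_te = mean(d$te_ms),
               std_te = stats::sd(d$te_ms), n_kept = nrow(d))
  }))
  agg <- agg[order(agg$subject_id, match(agg$label, .motion_labels), agg$duration_s), ]
  rownames(agg) <- NULL
  agg
}

#' Read and write trial and summary tables as CSV
#'
#' Plain-CSV round-trip of trial records and subject-by-condition summaries.
#' `read_trials()` also accepts externally collected data in the same
#' dialect (columns `subject_id`, `label`, `duration_s`, `trial_index`,
#' `rt_ms`, optionally `te_ms` and `excluded`).
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the data frame.
#' @export
write_trials <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "duration_s", "trial_index", "rt_ms")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("trial CSV is missing columns: ", paste(miss, collapse = ", "))
  if ("excluded" %in% names(d)) d$excluded <- as.logical(d$excluded)
  d
}

#' @rdname write_trials
#' @export
write_summaries <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_summaries <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
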