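# gravicept

Modelling the timing of manual interception of vertically looming targets:
when does the brain's internal model of gravity take over the time-to-contact
estimate, and how much do on-line optical variables contribute?

`gravicept` is aimed at researchers in sensorimotor control and Bayesian
psychophysics. It implements, end to end:

1. **Scene kinematics** — a virtual free-fall scene (ball dropped 8.945 m
   onto a ring above the observer's head) with twelve motion conditions:
   accelerations a ∈ {−g, 0, +g} × durations T ∈ {0.8, 0.9, 1.0, 1.1} s,
   matched on mean velocity by solving D = v₀T + ½aT² for each initial
   velocity, plus exact retinal size/looming traces θ(t), θ̇(t).
2. **Arrival-time predictors** — thirteen *gravity* predictors (extrapolate
   the remaining fall at 1g from an engagement time tₑ ∈ {0, 50, …, 600} ms:
   the predicted arrival is tₑ + τ with d = vτ + ½gτ²), and the *known-size
   (KS) optical* predictor (respond a motor delay T_ca = 150 ms after the
   looming rate θ̇ = s·v/d² crosses the threshold θ̇_th = s/(v̄·T_ca²)).
3. **A synthetic-response generator** — 32 subjects × 12 conditions × 20
   trials whose mean RTs follow a linear mixed model on a predictor
   (correlated random intercept + slope per subject), with timing-error
   computation, 2-SD outlier filtering and aggregation.
4. **Analysis** — repeated-measures ANOVA with Greenhouse–Geisser
   correction; Bayesian linear mixed regression (Gibbs sampling via JAGS)
   with Bayesian R², an engagement-time scan, and PSIS-LOO model comparison
   under the rule "ELPD difference > 4 and > its SE".

## Worked example

```r
library(gravicept)

# the 12 kinematic conditions and the predictor table
pt <- predictor_table()
m1g <- pt[pt$label == "minus_g", ]
cbind(m1g["duration_s"], round(m1g[c("g_0", "g_450", "optical")]))
#>   duration_s g_0 g_450 optical
#> 1        0.8 508   712     782
#> 2        0.9 528   754     877
#> 3        1.0 542   785     970
#> 4        1.1 551   805    1060
# a decelerating 1.1-s target would be intercepted at 551 ms if the gravity
# prior were engaged at onset, 805 ms if engaged at 450 ms — the true
# arrival is 1100 ms, so both are anticipations.

# simulate a cohort and analyse it
params <- generative_params(seed = 1)          # slope 0.99 on gravity-450
trials <- filter_outliers(compute_te(simulate_trials(params, pt)))
sm     <- aggregate_trials(trials)             # 384 subject-condition means

fit <- fit_mixed(sm, pt, gravity_col = "g_450", seed = 1)
fit$summary[2, c("term", "mean", "sd")]
#>          term      mean        sd
#> 2 slope_g_450 0.9776467 0.0127327
round(fit$bayes_r2$mean, 3)
#> [1] 0.962
# the fitted slope recovers the generative gain of 0.99 within two posterior
# SDs, and the model explains ~96% of the variance in the condition means.

# when was the gravity prior engaged?
scan <- scan_engagement_times(sm, pt, grid_ms = seq(300, 600, 50), seed = 1)
scan$best_time
#> [1] 450
# the R² profile across candidate engagement times peaks at the 450 ms the
# cohort was generated from.

# does optical information add predictive power? (none was generated here)
fit_opt <- fit_mixed(sm, pt, gravity_col = "g_450",
                     extra_cols = "optical", seed = 1)
compare_loo(fit, fit_opt)[c("elpd_diff", "se_diff", "significant")]
#> $elpd_diff
#> [1] -0.73
#> $se_diff
#> [1] 0.62
#> $significant
#> [1] FALSE
```

A thin command-line front end over the same functions lives in
`inst/cli/gravicept.R`
(`Rscript gravicept.R run-all --seed 1 --out results/`).

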