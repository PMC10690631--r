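#' Parameters of the known-size (KS) optical looming model
#'
#' The KS model triggers the interceptive action when the retinal dilation
#' rate crosses a threshold derived from the known physical size of the ball
#' and a fixed motor delay. `tca` is the time needed to execute the button
#' press once triggered; `window` is the interval, expressed in seconds
#' before arrival, over which the target velocity is averaged to set the
#' threshold.
#'
#' @param tca Motor execution delay (s).
#' @param window Two increasing times before arrival (s) bounding the
#'   velocity-averaging window; the default averages over 150-250 ms before
#'   the ball reaches the ring.
#' @return An object of class `ks_params`.
#' @export
ks_params <- function(tca = 0.150, window = c(0.150, 0.250)) {
  if (!is.numeric(tca) || tca <= 0) stop("tca must be a positive scalar (s)")
  if (length(window) != 2 || window[1] <= 0 || window[1] >= window[2])
    stop("window must be two increasing positive times before arrival (s)")
  structure(list(tca = tca, window = window), class = "ks_params")
}

#' Arrival-time predictor under the internal model of gravity
#'
#' Predicts when the ball reaches the ring under the assumption that, from
#' engagement time `t_e` onwards, it accelerates at 1g regardless of its true
#' kinematics. The trajectory is propagated under the true motion up to
#' `t_e`, then the remaining fall is extrapolated under gravity: the residual
#' time tau is the positive root of d_rem = v_e*tau + g*tau^2/2,
#' tau = (-v_e + sqrt(v_e^2 + 2*g*d_rem))/g. For targets that truly
#' accelerate at 1g the assumption is congruent with the motion, so the
#' prediction equals the true duration for every engagement time.
#'
#' @param condition A [motion_condition()] object.
#' @param t_e Engagement time of the gravity prior (s since motion onset).
#' @param geometry A [scene_geometry()] object.
#' @return Predicted arrival time in ms from motion onset.
#' @examples
#' mc <- motion_condition("minus_g", 1.1)
#' gravity_arrival_estimate(mc, 0)   # ~551 ms: strong anticipation
#' @export
gravity_arrival_estimate <- function(condition, t_e, geometry = scene_geometry()) {
  stopifnot(inherits(condition, "motion_condition"))
  if (t_e < 0) stop("t_e must be non-negative")
  if (condition$label == "plus_g") return(1000 * condition$duration)
  if (t_e >= condition$duration) return(1000 * condition$duration)
  st <- state_at(condition, t_e)
  d_rem <- st$distance_to_ring
  v_e <- st$velocity
  if (v_e <= 0) stop("velocity at engagement must be positive")
  g <- geometry$g
  disc <- v_e^2 + 2 * g * d_rem
  stopifnot(disc > 0)
  tau <- (-v_e + sqrt(disc)) / g
  1000 * (t_e + tau)
}

#' Grid of gravity predictors over engagement times
#'
#' Evaluates [gravity_arrival_estimate()] for every condition at each
#' engagement time on the grid (default 0 to 600 ms in 50-ms steps),
#' producing the family of gravity predictors used by the engagement-time
#' scan.
#'
#' @param conditions A condition table from [build_condition_table()].
#' @param t_grid Engagement times (s).
#' @param geometry A [scene_geometry()] object.
#' @return A data frame with the condition key columns (`label`,
#'   `duration_s`) followed by one column `g_<ms>` per engagement time, in ms.
#' @export
gravity_predictor_grid <- function(conditions,
                                   t_grid = seq(0, 0.6, by = 0.05),
                                   geometry = scene_geometry()) {
  vals <- sapply(t_grid, function(te) {
    vapply(seq_len(nrow(conditions)), function(i) {
      mc <- motion_condition(conditions$label[i], conditions$duration_s[i], geometry)
      gravity_arrival_estimate(mc, te, geometry)
    }, numeric(1))
  })
  vals <- matrix(vals, nrow = nrow(conditions))
  colnames(vals) <- paste0("g_", round(1000 * t_grid))
  cbind(conditions[, c("label", "duration_s")], as.data.frame(vals))
}

#' Mean target velocity shortly before arrival
#'
#' Time-average of the downward velocity over the window `[T - window[2],
#' T - window[1]]`. Because velocity is linear in time for these constant-
#' acceleration profiles, the average equals the velocity at the window
#' midpoint.
#'
#' @param condition A [motion_condition()] object.
#' @param window Two increasing times before arrival (s), as in [ks_params()].
#' @return Mean velocity (m/s).
#' @export
mean_prearrival_velocity <- function(condition, window = c(0.150, 0.250)) {
  stopifnot(inherits(condition, "motion_condition"))
  if (window[2] > condition$duration)
    stop("averaging window starts before motion onset")
  t1 <- condition$duration - window[2]
  t2 <- condition$duration - window[1]
  # exact time-average of the linear v(t) = v0 + a t over [t1, t2]
  condition$v0 + condition$accel * (t1 + t2) / 2
}

#' Arrival-time predictor from the KS optical looming model
#'
#' Computes the retinal dilation-rate threshold theta_dot_th = s/(v_bar *
#' tca^2), where s is the ball size and v_bar the mean pre-arrival velocity,
#' then finds the earliest time at which the looming signal theta_dot =
#' s*v(t)/d(t)^2 (small-angle form, d = ball-to-ring distance) reaches the
#' threshold, by bracketed root finding. The predicted response lands one
#' motor delay after the trigger.
#'
#' For constant-velocity targets the threshold is crossed exactly `tca`
#' before arrival, so the prediction matches the true duration; decelerating
#' targets cross early (anticipation), accelerating ones late.
#'
#' @param condition A [motion_condition()] object.
#' @param ks A [ks_params()] object.
#' @param geometry A [scene_geometry()] object.
#' @return Predicted arrival time in ms from motion onset.
#' @export
optical_arrival_estimate <- function(condition, ks = ks_params(),
                                     geometry = scene_geometry()) {
  stopifnot(inherits(condition, "motion_condition"), inherits(ks, "ks_params"))
  s <- geometry$ball_diameter
  v_bar <- mean_prearrival_velocity(condition, ks$window)
  th_dot_th <- s / (v_bar * ks$tca^2)
  loom <- function(t) {
    st <- state_at(condition, t)
    s * st$velocity / st$distance_to_ring^2 - th_dot_th
  }
  # theta_dot diverges as d -> 0, so a crossing always exists if loom(0) < 0;
  # bracket the root away from the d = 0 singularity
  upper <- condition$duration - 1e-9
  if (loom(0) >= 0)
    stop("dilation-rate threshold already exceeded at motion onset")
  root <- stats::uniroot(loom, c(0, upper), tol = 1e-12)
  1000 * (root$root + ks$tca)
}

#' Full predictor table: gravity family plus KS optical column
#'
#' @param geometry A [scene_geometry()] object.
#' @param t_grid Engagement-time grid (s) for the gravity predictors.
#' @param ks A [ks_params()] object for the optical predictor.
#' @param durations Motion durations (s).
#' @return A data frame with `label`, `duration_s`, one `g_<ms>` column per
#'   engagement time and an `optical` column, all in ms at full precision.
#' @examples
#' pt <- predictor_table()
#' round(pt[pt$label == "zero_g", c("g_0", "optical")])
#' @export
predictor_table <- function(geometry = scene_geometry(),
                            t_grid = seq(0, 0.6, by = 0.05),
                            ks = ks_params(),
                            durations = c(0.8, 0.9, 1.0, 1.1)) {
  conds <- build_condition_table(geometry, durations)
  out <- gravity_predictor_grid(conds, t_grid, geometry)
  out$optical <- vapply(seq_len(nrow(conds)), function(i) {
    mc <- motion_condition(conds$label[i], conds$duration_s[i], geometry)
    optical_arrival_estimate(mc, ks, geometry)
  }, numeric(1))
  out
}

#' Write a predictor table as CSV (display) and JSON (full precision)
#'
#' The CSV view rounds to the nearest ms and orders rows by acceleration
#' label then descending duration; the optional JSON sidecar keeps full
#' precision for downstream regression use.
#'
#' @param table A predictor table from [predictor_table()].
#' @param path CSV file path.
#' @param json_path Optional JSON file path.
#' @return `path`, invisibly.
#' @export
write_predictor_table <- function(table, path, json_path = NULL) {
  disp <- table[order(match(table$label, c("minus_g", "zero_g", "plus_g")),
                      -table$duration_s), ]
  num <- setdiff(names(disp), c("label", "duration_s"))
  disp[num] <- lapply(disp[num], function(x) round(x))
  utils::write.csv(disp, path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(table, json_path, digits = NA, dataframe = "columns")
  invisible(path)
}
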