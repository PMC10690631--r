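#' Virtual free-fall scene geometry
#'
#' Defines the fixed lengths of the interception scene: a ball is released
#' from a point high above the observer and must be intercepted as it crosses
#' a ring held just above the observer's head. All lengths are in meters,
#' measured as heights above the ground unless stated otherwise. Downward is
#' the positive motion axis throughout the package.
#'
#' @param release_height Height of the release point above the ground (m).
#' @param ring_height Height of the interception ring above the ground (m).
#' @param ball_diameter Physical diameter of the ball (m).
#' @param eye_ring_offset Distance from the observer's eye to the ring (m);
#'   the ring sits this far above the eye, so the eye-to-ball distance is
#'   the ball-to-ring distance plus this offset.
#' @param disappearance_offset Distance below the ring at which the ball
#'   leaves the field of view (m). Not used by the kinematics, kept for
#'   completeness of the scene description.
#' @param g Gravitational acceleration magnitude (m/s^2).
#'
#' @return An object of class `scene_geometry` (a named list).
#' @examples
#' geom <- scene_geometry()
#' drop_distance(geom)
#' @export
scene_geometry <- function(release_height = 9.72,
                           ring_height = 0.775,
                           ball_diameter = 0.07,
                           eye_ring_offset = 0.5,
                           disappearance_offset = 0.40,
                           g = 9.8) {
  geom <- list(
    release_height = release_height,
    ring_height = ring_height,
    ball_diameter = ball_diameter,
    eye_ring_offset = eye_ring_offset,
    disappearance_offset = disappearance_offset,
    g = g
  )
  if (!all(vapply(geom, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))))
    stop("all scene_geometry fields must be finite numeric scalars")
  if (geom$ring_height <= 0) stop("ring_height must be positive")
  if (geom$release_height <= geom$ring_height)
    stop("release_height must exceed ring_height (the ball must fall towards the ring)")
  if (geom$ball_diameter <= 0 || geom$eye_ring_offset <= 0 ||
      geom$disappearance_offset < 0 || geom$g <= 0)
    stop("lengths and g must be positive")
  structure(geom, class = "scene_geometry")
}

#' @export
print.scene_geometry <- function(x, ...) {
  cat("Scene geometry (m):\n")
  cat(sprintf("  release height     %.3f\n", x$release_height))
  cat(sprintf("  ring height        %.3f\n", x$ring_height))
  cat(sprintf("  drop distance      %.3f\n", drop_distance(x)))
  cat(sprintf("  ball diameter      %.3f\n", x$ball_diameter))
  cat(sprintf("  eye-ring offset    %.3f\n", x$eye_ring_offset))
  cat(sprintf("  g (m/s^2)          %.2f\n", x$g))
  invisible(x)
}

#' Read scene geometry from a YAML configuration file
#'
#' The file may contain a `scene:` block whose entries override any
#' [scene_geometry()] field; missing entries keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `scene_geometry` object.
#' @export
scene_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  over <- cfg$scene
  if (is.null(over)) return(scene_geometry())
  allowed <- names(formals(scene_geometry))
  bad <- setdiff(names(over), allowed)
  if (length(bad)) stop("unknown scene fields in config: ", paste(bad, collapse = ", "))
  do.call(scene_geometry, over)
}

#' Vertical distance covered by the ball
#'
#' @param geometry A [scene_geometry()] object.
#' @return Drop distance from release point to ring (m).
#' @export
drop_distance <- function(geometry) {
  stopifnot(inherits(geometry, "scene_geometry"))
  geometry$release_height - geometry$ring_height
}

# canonical acceleration labels: downward is positive, so "minus_g" is a
# deceleration of the downward speed
.motion_labels <- c("minus_g", "zero_g", "plus_g")

.label_accel <- function(label, g) {
  label <- match.arg(label, .motion_labels)
  switch(label, minus_g = -g, zero_g = 0, plus_g = g)
}

#' Initial velocity for a matched-mean-velocity motion condition
#'
#' Solves for the initial downward velocity v0 such that the ball covers the
#' full drop distance D in exactly `duration` seconds under constant
#' acceleration a: D = v0*T + a*T^2/2, i.e. v0 = (D - a*T^2/2)/T. Because all
#' three acceleration profiles cover the same distance in the same time,
#' their mean velocity D/T is identical by construction.
#'
#' @param label One of `"minus_g"`, `"zero_g"`, `"plus_g"`.
#' @param duration Motion duration T (s).
#' @param geometry A [scene_geometry()] object.
#' @return Initial downward velocity v0 (m/s).
#' @export
solve_initial_velocity <- function(label, duration, geometry = scene_geometry()) {
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("duration must be a positive scalar (s)")
  a <- .label_accel(label, geometry$g)
  D <- drop_distance(geometry)
  v0 <- (D - 0.5 * a * duration^2) / duration
  vt <- v0 + a * duration
  if (v0 <= 0 || vt <= 0)
    stop(sprintf("unphysical condition: v0 = %.3f, vt = %.3f (both must be > 0)", v0, vt))
  v0
}

#' Construct one target motion condition
#'
#' @inheritParams solve_initial_velocity
#' @return An object of class `motion_condition` with fields `label`,
#'   `accel` (signed, m/s^2, downward positive), `duration` (s), `v0`, `vt`
#'   (m/s) and `drop` (m).
#' @export
motion_condition <- function(label, duration, geometry = scene_geometry()) {
  label <- match.arg(label, .motion_labels)
  v0 <- solve_initial_velocity(label, duration, geometry)
  a <- .label_accel(label, geometry$g)
  structure(list(
    label = label,
    accel = a,
    duration = duration,
    v0 = v0,
    vt = v0 + a * duration,
    drop = drop_distance(geometry)
  ), class = "motion_condition")
}

#' @export
print.motion_condition <- function(x, ...) {
  cat(sprintf("Motion condition %s: T = %.2f s, a = %+.1f m/s^2, v0 = %.3f, vt = %.3f m/s\n",
              x$label, x$duration, x$accel, x$v0, x$vt))
  invisible(x)
}

#' Build the full table of target kinematic conditions
#'
#' Crosses the three acceleration labels with the four motion durations
#' (0.8-1.1 s) and solves each initial velocity so that every condition covers
#' the drop distance exactly in its nominal duration. Within each duration
#' the mean velocity is therefore identical across acceleration levels.
#'
#' @param geometry A [scene_geometry()] object.
#' @param durations Motion durations (s).
#' @return A data frame with one row per condition: `label`, `duration_s`,
#'   `accel_ms2`, `v0_ms`, `vt_ms` (full precision).
#' @examples
#' ct <- build_condition_table()
#' round(ct$v0_ms, 1)
#' @export
build_condition_table <- function(geometry = scene_geometry(),
                                  durations = c(0.8, 0.9, 1.0, 1.1)) {
  grid <- expand.grid(duration_s = durations, label = .motion_labels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    mc <- motion_condition(grid$label[i], grid$duration_s[i], geometry)
    data.frame(label = mc$label, duration_s = mc$duration, accel_ms2 = mc$accel,
               v0_ms = mc$v0, vt_ms = mc$vt)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kinematic state of the target at a given time
#'
#' @param condition A [motion_condition()] object.
#' @param t Time since motion onset (s); may be a vector. Must lie in
#'   `[0, duration]`.
#' @return A data frame with columns `t`, `distance_to_ring` (m, remaining
#'   ball-to-ring distance) and `velocity` (m/s, downward).
#' @export
state_at <- function(condition, t) {
  stopifnot(inherits(condition, "motion_condition"))
  if (any(t < -1e-12 | t > condition$duration + 1e-12))
    stop(sprintf("t must lie within [0, %.3f] s", condition$duration))
  t <- pmin(pmax(t, 0), condition$duration)
  d <- condition$drop - (condition$v0 * t + 0.5 * condition$accel * t^2)
  v <- condition$v0 + condition$accel * t
  data.frame(t = t, distance_to_ring = pmax(d, 0), velocity = v)
}

#' Retinal image size and dilation rate along a trajectory
#'
#' Computes the angular size theta = 2*atan(s / (2*d_eye)) of the approaching
#' ball and its dilation rate, where d_eye is the eye-to-ball distance
#' (ball-to-ring distance plus the eye-ring offset). The dilation rate uses
#' the exact analytic derivative s*v / (d_eye^2 + s^2/4).
#'
#' @param condition A [motion_condition()] object.
#' @param geometry A [scene_geometry()] object.
#' @param dt Sampling step (s), default 1 ms.
#' @return A data frame with columns `t` (s), `theta` (rad) and `theta_dot`
#'   (rad/s).
#' @export
retinal_trace <- function(condition, geometry = scene_geometry(), dt = 0.001) {
  stopifnot(inherits(condition, "motion_condition"))
  if (dt <= 0) stop("dt must be positive")
  t <- seq(0, condition$duration, by = dt)
  st <- state_at(condition, t)
  s <- geometry$ball_diameter
  d_eye <- st$distance_to_ring + geometry$eye_ring_offset
  if (any(d_eye <= 0))
    stop("eye-to-ball distance reaches zero inside the sampled interval")
  theta <- 2 * atan(s / (2 * d_eye))
  theta_dot <- s * st$velocity / (d_eye^2 + s^2 / 4)
  data.frame(t = t, theta = theta, theta_dot = theta_dot)
}

#' Write / read a condition table as CSV
#'
#' `write_condition_table()` stores the table at full precision (bit-exact
#' round-trip through [read_condition_table()]); with `rounded = TRUE` it
#' writes a display view with velocities rounded to 0.1 m/s.
#'
#' @param table A condition table from [build_condition_table()].
#' @param path File path.
#' @param rounded Write the rounded display view instead of full precision.
#' @return `write_condition_table()` returns `path` invisibly;
#'   `read_condition_table()` returns the table.
#' @export
write_condition_table <- function(table, path, rounded = FALSE) {
  out <- table
  if (rounded) {
    out$v0_ms <- round(out$v0_ms, 1)
    out$vt_ms <- round(out$vt_ms, 1)
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    # format at full double precision so the round-trip is bit-exact
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_condition_table
#' @export
read_condition_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
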