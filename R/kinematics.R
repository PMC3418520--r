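#' Lateral plant parameters
#'
#' A deliberately simple stand-in for the arm holding the manipulandum: a point
#' mass with linear arm impedance, plus the error-clamp channel implemented as
#' a stiff spring-damper (1000 N/m, 50 Ns/m) acting only on clamp trials.
#'
#' @param mass Hand + handle point mass (kg).
#' @param arm_stiffness Arm lateral stiffness (N/m).
#' @param arm_damping Arm lateral damping (Ns/m).
#' @param channel_stiffness Channel wall stiffness (N/m).
#' @param channel_damping Channel wall damping (Ns/m).
#' @return A list of class `plant_params`.
#' @export
plant_params <- function(mass = 1, arm_stiffness = 50, arm_damping = 10,
                         channel_stiffness = 1000, channel_damping = 50) {
  p <- list(mass = mass, arm_stiffness = arm_stiffness,
            arm_damping = arm_damping, channel_stiffness = channel_stiffness,
            channel_damping = channel_damping)
  if (any(unlist(p) <= 0)) stop("plant parameters must be strictly positive",
                                call. = FALSE)
  class(p) <- "plant_params"
  p
}

.trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

.cumtrapz <- function(t, y) {
  c(0, cumsum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

#' Minimum-jerk forward velocity profile
#'
#' The standard quartic speed profile of a point-to-point reach: bell-shaped,
#' time-symmetric, zero speed and zero acceleration at both endpoints, peak
#' speed 1.875 * distance / duration at mid-movement. The sampled profile is
#' rescaled (by ~1 part in 5e8 at 200 Hz) so its trapezoidal integral equals
#' `distance` exactly.
#'
#' @param distance Reach distance (m). Default 0.13 m.
#' @param duration Movement duration (s). Default 0.45 s, so that peak speed
#'   is ~0.54 m/s, inside the observed 53.1-57.8 cm/s range.
#' @param dt Sample interval (s); default 1/200 (200 Hz).
#' @return A list of class `reach_profile` with `t`, `vy` (m/s), `y` (m),
#'   `dt`, `distance`, `duration`.
#' @examples
#' p <- minjerk_profile(0.1, 0.5)
#' max(p$vy)  # ~0.375 m/s
#' @export
minjerk_profile <- function(distance = 0.13, duration = 0.45, dt = 1 / 200) {
  if (distance <= 0) stop("distance must be positive", call. = FALSE)
  if (dt <= 0 || dt >= duration) stop("need 0 < dt < duration", call. = FALSE)
  n <- floor(duration / dt + 1e-9)
  t <- (0:n) * dt
  tau <- t / duration
  vy <- distance / duration * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  vy <- vy * distance / .trapz(t, vy)
  structure(list(t = t, vy = vy, y = .cumtrapz(t, vy), dt = dt,
                 distance = distance, duration = duration),
            class = "reach_profile")
}

#' Viscous field force for a reach
#'
#' The lateral force of a viscous curl field of amplitude `B`: proportional to
#' forward hand speed and perpendicular to it, `fx(t) = B * vy(t)`; the
#' forward force component is zero.
#'
#' @param B Field amplitude (Ns/m), >= 0.
#' @param profile A [minjerk_profile()] (or anything with a `vy` series).
#' @return Lateral force series (N), same length as `profile$vy`.
#' @export
field_force <- function(B, profile) {
  if (B < 0) stop("B must be non-negative", call. = FALSE)
  B * profile$vy
}

# RK4 integration of the LTI lateral plant m x'' + b x' + k x = u(t), with the
# drive sampled at dt and interpolated linearly inside a step. Returns x and
# xdot at the sample instants.
.simulate_lateral <- function(drive, dt, mass, stiffness, damping, substeps = 1L) {
  lam <- max(Mod(eigen(matrix(c(0, 1, -stiffness / mass, -damping / mass),
                              2, 2, byrow = TRUE),
                       only.values = TRUE)$values))
  h <- dt / substeps
  if (lam * h > 2.5) {
    stop("lateral integration unstable (|lambda|*dt = ",
         signif(lam * h, 3), " > 2.5): use a smaller dt or more substeps",
         call. = FALSE)
  }
  n <- length(drive)
  x <- numeric(n); v <- numeric(n)
  deriv <- function(x, v, u) c(v, (u - stiffness * x - damping * v) / mass)
  for (i in seq_len(n - 1L)) {
    u0 <- drive[i]; u1 <- drive[i + 1L]
    xi <- x[i]; vi <- v[i]
    for (s in seq_len(substeps)) {
      a0 <- u0 + (u1 - u0) * (s - 1) / substeps
      ah <- u0 + (u1 - u0) * (s - 0.5) / substeps
      a1 <- u0 + (u1 - u0) * s / substeps
      k1 <- deriv(xi, vi, a0)
      k2 <- deriv(xi + h / 2 * k1[1], vi + h / 2 * k1[2], ah)
      k3 <- deriv(xi + h / 2 * k2[1], vi + h / 2 * k2[2], ah)
      k4 <- deriv(xi + h * k3[1], vi + h * k3[2], a1)
      xi <- xi + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      vi <- vi + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    }
    x[i + 1L] <- xi; v[i + 1L] <- vi
  }
  list(x = x, xdot = v)
}

.trial_record <- function(trial_type, B, B_hat, profile, fx, x) {
  structure(list(trial_type = trial_type, B = B, B_hat = B_hat,
                 dt = profile$dt, vy = profile$vy, fx = fx, x = x),
            class = "trial_record")
}

#' Simulate one force-field (or null-field) reach
#'
#' The learner expresses a feedforward lateral force `B_hat * vy(t)` against a
#' field `B * vy(t)`; the mismatch `(B - B_hat) * vy(t)` drives the lateral
#' mass-spring-damper plant and produces a movement error. A fully compensated
#' field (`B_hat = B`) yields zero lateral displacement.
#'
#' @param B_hat Learner feedforward gain (Ns/m).
#' @param B Field amplitude (Ns/m); 0 for a null-field trial.
#' @param profile A [minjerk_profile()].
#' @param plant A [plant_params()].
#' @param substeps RK4 substeps per sample (increase for stiff plants).
#' @return A `trial_record`: `vy`, `fx` (the subject's expressed force
#'   `B_hat * vy`), `x` (lateral displacement, m), plus metadata. The applied
#'   field force is `B * vy`.
#' @export
simulate_field_trial <- function(B_hat, B, profile, plant = plant_params(),
                                 substeps = 1L) {
  drive <- (B - B_hat) * profile$vy
  sim <- .simulate_lateral(drive, profile$dt, plant$mass,
                           plant$arm_stiffness, plant$arm_damping, substeps)
  .trial_record(if (B == 0) "null_field" else "force_field", B, B_hat,
                profile, B_hat * profile$vy, sim$x)
}

#' Simulate one error-clamp (force-channel) reach
#'
#' The channel adds a stiff spring-damper to the lateral plant, clamping the
#' lateral error near zero; the force the hand presses into the channel wall
#' (`channel_stiffness * x + channel_damping * xdot`) is recorded as the
#' subject's expressed lateral force. With the default plant the wall force at
#' maximum speed approximates `B_hat * max(vy)` to within ~5% (the arm's own
#' impedance absorbs the remainder).
#'
#' @inheritParams simulate_field_trial
#' @return A `trial_record` with `fx` = wall force (N) and `x` = residual
#'   lateral displacement (m).
#' @export
simulate_clamp_trial <- function(B_hat, profile, plant = plant_params(),
                                 substeps = 1L) {
  drive <- B_hat * profile$vy
  sim <- .simulate_lateral(drive, profile$dt, plant$mass,
                           plant$arm_stiffness + plant$channel_stiffness,
                           plant$arm_damping + plant$channel_damping, substeps)
  wall <- plant$channel_stiffness * sim$x + plant$channel_damping * sim$xdot
  .trial_record("error_clamp", NA_real_, B_hat, profile, wall, sim$x)
}
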