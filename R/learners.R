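#' Create a learner state
#'
#' The internal state of a synthetic subject: the current feedforward gain
#' estimate `B_hat` (Ns/m), a window of recently experienced field amplitudes,
#' and the learner's parameters.
#'
#' @param B_hat Initial feedforward gain (Ns/m).
#' @param history Numeric vector of recently experienced amplitudes (most
#'   recent last); length is capped at `params$k`.
#' @param params Learner parameters: `k` (window length), `eta` (learning
#'   rate), `A` (retention), `clamp_retention` (multiplier applied to `B_hat`
#'   on error-clamp trials; 1 = frozen state, the default), `law`.
#' @return A list of class `learner_state`.
#' @export
new_learner_state <- function(B_hat = 0, history = numeric(0), params = list()) {
  stopifnot(is.finite(B_hat))
  defaults <- list(k = 4L, eta = 0.3, A = 1, clamp_retention = 1, law = "fir")
  params <- utils::modifyList(defaults, params)
  if (length(history) > params$k) {
    history <- utils::tail(history, params$k)
  }
  structure(list(B_hat = B_hat, history = history, params = params),
            class = "learner_state")
}

#' Update an averaging learner after one trial
#'
#' Two selectable averaging laws for the hypothesis that the motor system
#' predicts the next perturbation as a weighted sum of past experiences:
#' \describe{
#'   \item{`"fir"`}{`B_hat` = mean of the last `k` experienced amplitudes
#'     (finite moving-average window).}
#'   \item{`"single_rate"`}{`B_hat <- A * B_hat + eta * (experienced_B -
#'     B_hat)` (single-rate state-space update with retention `A` and learning
#'     rate `eta`).}
#' }
#' On error-clamp trials no amplitude is experienced: the state is frozen by
#' default (`clamp_retention = 1`), or decayed by `clamp_retention < 1`.
#'
#' @param state A [new_learner_state()].
#' @param experienced_B Field amplitude experienced on the trial (Ns/m; 0 for
#'   null-field trials, ignored on clamp trials).
#' @param trial_type One of `"force_field"`, `"null_field"`, `"error_clamp"`.
#' @param law Averaging law; defaults to `state$params$law`.
#' @return The updated `learner_state`.
#' @examples
#' s <- new_learner_state(params = list(k = 4))
#' for (b in 1:4) s <- averager_update(s, b, "force_field")
#' s$B_hat  # 2.5, the mean of the sequence
#' @export
averager_update <- function(state, experienced_B,
                            trial_type = c("force_field", "null_field",
                                           "error_clamp"),
                            law = state$params$law) {
  trial_type <- match.arg(trial_type)
  if (trial_type == "error_clamp") {
    state$B_hat <- state$params$clamp_retention * state$B_hat
    return(state)
  }
  law <- match.arg(law, c("fir", "single_rate"))
  if (law == "fir") {
    state$history <- utils::tail(c(state$history, experienced_B),
                                 state$params$k)
    state$B_hat <- mean(state$history)
  } else {
    state$B_hat <- state$params$A * state$B_hat +
      state$params$eta * (experienced_B - state$B_hat)
  }
  state
}

#' Predict the next amplitude by linear extrapolation
#'
#' Fits an ordinary-least-squares line through `(index, amplitude)` pairs of
#' the recent history and evaluates it one step ahead — the "predict the
#' future" hypothesis. For the embedded sequence 1, 2, 3, 4 Ns/m this yields
#' 5 Ns/m, the next term of the series.
#'
#' @param history Numeric vector of at least 2 recently experienced
#'   amplitudes, oldest first.
#' @return Predicted next amplitude (Ns/m).
#' @examples
#' extrapolator_predict(c(1, 2, 3, 4))  # 5
#' @export
extrapolator_predict <- function(history) {
  n <- length(history)
  if (n < 2L) stop("extrapolation needs a history of at least 2 amplitudes",
                   call. = FALSE)
  x <- seq_len(n)
  slope <- sum((x - mean(x)) * (history - mean(history))) /
    sum((x - mean(x))^2)
  mean(history) + slope * (n + 1 - mean(x))
}

#' Update an extrapolating learner after one trial
#'
#' Pushes the experienced amplitude into the window and sets `B_hat` to the
#' one-step-ahead OLS extrapolation of the window contents. Clamp trials
#' freeze the state (as for [averager_update()]).
#'
#' @inheritParams averager_update
#' @return The updated `learner_state`.
#' @export
extrapolator_update <- function(state, experienced_B,
                                trial_type = c("force_field", "null_field",
                                               "error_clamp")) {
  trial_type <- match.arg(trial_type)
  if (trial_type == "error_clamp") {
    state$B_hat <- state$params$clamp_retention * state$B_hat
    return(state)
  }
  state$history <- utils::tail(c(state$history, experienced_B),
                               state$params$k)
  n <- length(state$history)
  state$B_hat <- if (n >= 2L) extrapolator_predict(state$history)
                 else if (n == 1L) state$history else 0
  state
}

#' Registered synthetic learners
#'
#' @return Character vector of learner names accepted by [run_subject()]:
#'   `"averager_fir"` (moving-average window), `"averager_single_rate"`
#'   (single-rate state-space), `"extrapolator"` (OLS trend extrapolation).
#' @export
learner_registry <- function() {
  c("averager_fir", "averager_single_rate", "extrapolator")
}

#' Construct a learner (initial state + update rule)
#'
#' @param name A name from [learner_registry()].
#' @param params Parameter overrides: `k` (window, default 4), `eta` (default
#'   0.3), `A` (default 1), `clamp_retention` (default 1), `noise_sd`
#'   (fractional execution noise sd, default 0.05), `baseline_seeding` (seed
#'   the window with `k` zeros at start, default TRUE — the prior baseline of
#'   the zero force field then enters the average).
#' @return A list with `name`, `params`, `init()` and
#'   `update(state, experienced_B, trial_type)`.
#' @export
make_learner <- function(name, params = list()) {
  if (!name %in% learner_registry()) {
    stop("unknown learner '", name, "'; registered learners: ",
         paste(learner_registry(), collapse = ", "), call. = FALSE)
  }
  defaults <- list(k = 4L, eta = 0.3, A = 1, clamp_retention = 1,
                   noise_sd = 0.05, baseline_seeding = TRUE)
  params <- utils::modifyList(defaults, params)
  params$law <- switch(name,
                       averager_fir = "fir",
                       averager_single_rate = "single_rate",
                       extrapolator = "fir")  # law unused by extrapolator
  init <- function() {
    hist0 <- if (isTRUE(params$baseline_seeding) &&
                 name != "averager_single_rate") rep(0, params$k)
             else numeric(0)
    new_learner_state(B_hat = 0, history = hist0, params = params)
  }
  update <- switch(name,
    averager_fir = function(state, b, type) averager_update(state, b, type, law = "fir"),
    averager_single_rate = function(state, b, type) averager_update(state, b, type, law = "single_rate"),
    extrapolator = extrapolator_update)
  list(name = name, params = params, init = init, update = update)
}

#' Simulation configuration for a session
#'
#' @param distance Reach distance (m).
#' @param duration Movement duration (s).
#' @param dt Sample interval (s).
#' @param plant A [plant_params()].
#' @param substeps RK4 substeps per sample.
#' @return A list.
#' @export
sim_config <- function(distance = 0.13, duration = 0.45, dt = 1 / 200,
                       plant = plant_params(), substeps = 1L) {
  list(distance = distance, duration = duration, dt = dt, plant = plant,
       substeps = substeps)
}

#' Run one synthetic subject through a schedule
#'
#' Iterates the schedule in order. Before each trial the learner's current
#' gain `B_hat` is perturbed by multiplicative Gaussian execution noise
#' (`B_hat_used = B_hat * (1 + eps)`, `eps ~ N(0, noise_sd)`), the trial is
#' simulated (field/null trials through the lateral plant, clamp trials
#' through the channel), and the learner state is updated with the
#' experienced amplitude (the scheduled `B` on force trials, 0 on null
#' trials; clamp trials freeze the state).
#'
#' Because the lateral plant is linear and time-invariant, trial responses are
#' computed by scaling unit responses precomputed once per session (field
#' displacement scales with `B - B_hat_used`, clamp wall force with
#' `B_hat_used`); this is exact up to floating point and is verified against
#' direct RK4 simulation in the test suite.
#'
#' @param schedule A [build_schedule()] result.
#' @param learner A learner name from [learner_registry()], or a list
#'   `list(name = , params = )`, or a [make_learner()] result.
#' @param config A [sim_config()].
#' @param seed Integer seed; the session is deterministic given the seed.
#' @param keep_series Which trials keep full time series in `records`:
#'   `"clamp"` (default; enough for force-profile analysis), `"all"`, or
#'   `"none"` (summary scalars only).
#' @return An object of class `reach_session`: list with `summary` (one row
#'   per trial: `index`, `phase`, `trial_type`, `B`, `sequence_id`,
#'   `block_id`, `B_hat` (pre-trial estimate), `B_hat_used` (noise-perturbed
#'   executed gain), `fx_max_speed`, `fx_peak`, `movement_error`), `records`
#'   (named list of `trial_record`s, names = 0-based trial index), `profile`,
#'   `learner_name`, `params`, and `seed`.
#' @export
run_subject <- function(schedule, learner, config = sim_config(), seed = 1L,
                        keep_series = c("clamp", "all", "none")) {
  keep_series <- match.arg(keep_series)
  if (is.character(learner)) learner <- make_learner(learner)
  if (is.null(learner$init)) learner <- make_learner(learner$name, learner$params)
  tr <- schedule$trials
  n <- nrow(tr)

  profile <- minjerk_profile(config$distance, config$duration, config$dt)
  plant <- config$plant
  unit_field <- simulate_field_trial(0, 1, profile, plant, config$substeps)
  unit_clamp <- simulate_clamp_trial(1, profile, plant, config$substeps)
  i_max <- which.max(profile$vy)
  noise_sd <- learner$params$noise_sd

  B_hat_pre <- numeric(n); B_hat_used <- numeric(n)
  fx_max <- numeric(n); fx_peak <- numeric(n); merr <- numeric(n)
  records <- list()

  withr::with_seed(as.integer(seed), {
    state <- learner$init()
    for (i in seq_len(n)) {
      type <- tr$trial_type[i]
      B <- tr$B[i]
      bh <- state$B_hat
      bhu <- bh * (1 + stats::rnorm(1, 0, noise_sd))
      B_hat_pre[i] <- bh; B_hat_used[i] <- bhu

      if (type == "error_clamp") {
        fx <- bhu * unit_clamp$fx
        x <- bhu * unit_clamp$x
      } else {
        fx <- bhu * profile$vy
        x <- (B - bhu) * unit_field$x
      }
      fx_max[i] <- fx[i_max]
      fx_peak[i] <- fx[which.max(abs(fx))]
      merr[i] <- x[i_max]

      if (keep_series == "all" ||
          (keep_series == "clamp" && type == "error_clamp")) {
        records[[as.character(tr$index[i])]] <-
          .trial_record(type, B, bhu, profile, fx, x)
      }

      experienced <- if (type == "force_field") B else 0
      state <- learner$update(state, experienced, type)
    }
  })

  summary <- tibble::tibble(
    index = tr$index, phase = tr$phase, trial_type = tr$trial_type,
    B = tr$B, sequence_id = tr$sequence_id, block_id = tr$block_id,
    B_hat = B_hat_pre, B_hat_used = B_hat_used,
    fx_max_speed = fx_max, fx_peak = fx_peak, movement_error = merr
  )
  structure(list(summary = summary, records = records, profile = profile,
                 learner_name = learner$name, params = learner$params,
                 seed = as.integer(seed)),
            class = "reach_session")
}

#' @export
print.reach_session <- function(x, ...) {
  cat("reach_session:", nrow(x$summary), "trials, learner ", x$learner_name,
      " (seed ", x$seed, "), ", length(x$records), " stored series\n", sep = "")
  invisible(x)
}

#' Run a cohort of synthetic subjects
#'
#' @param schedule A [build_schedule()] result (shared by all subjects, as in
#'   the experiment: block order fixed across subjects).
#' @param learner As in [run_subject()].
#' @param n_subjects Number of subjects (default 10).
#' @param config A [sim_config()].
#' @param seed Base seed; subject `i` runs with seed `seed + i - 1`.
#' @param keep_series Passed to [run_subject()].
#' @return List of `reach_session` objects.
#' @export
run_cohort <- function(schedule, learner, n_subjects = 10,
                       config = sim_config(), seed = 1L,
                       keep_series = c("clamp", "all", "none")) {
  keep_series <- match.arg(keep_series)
  lapply(seq_len(n_subjects), function(i) {
    run_subject(schedule, learner, config, seed = as.integer(seed) + i - 1L,
                keep_series = keep_series)
  })
}
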