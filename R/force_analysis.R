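#' Full-compensatory ("perfect") force profile
#'
#' The lateral force that would exactly cancel a viscous field of amplitude
#' `B` on a trial with forward speed `vy`: `B * vy(t)`.
#'
#' @param B Field amplitude (Ns/m), >= 0.
#' @param vy Forward speed series (m/s).
#' @return Force series (N), same length as `vy`.
#' @export
perfect_force <- function(B, vy) {
  if (B < 0) stop("B must be non-negative", call. = FALSE)
  B * vy
}

#' Lateral force at maximum speed
#'
#' The force sample at the instant of peak forward speed — for
#' velocity-proportional fields this coincides with the peak force. Ties in
#' `vy` are broken by the earliest index.
#'
#' @param fx Lateral force series (N).
#' @param vy Forward speed series (m/s), same length.
#' @return Force (N) at `which.max(vy)`.
#' @export
force_at_max_speed <- function(fx, vy) {
  if (length(fx) == 0L || length(fx) != length(vy)) {
    stop("fx and vy must be non-empty series of equal length", call. = FALSE)
  }
  fx[which.max(vy)]
}

#' Adaptation coefficient
#'
#' Slope of the through-origin linear regression of the actually exerted
#' force onto the full-compensatory force: `a = <F_actual, F_FC> /
#' <F_FC, F_FC>`. Equals 1 when the exerted force is identical to the perfect
#' force, 0 when unrelated. No intercept is fitted (the model `F_Actual =
#' a * F_FC` has none).
#'
#' @param F_actual Measured lateral force series (N).
#' @param F_FC Full-compensatory force series (N), not identically zero.
#' @return The adaptation coefficient `a` (dimensionless).
#' @export
adaptation_coefficient <- function(F_actual, F_FC) {
  if (length(F_actual) != length(F_FC)) {
    stop("series must have equal length", call. = FALSE)
  }
  denom <- sum(F_FC^2)
  if (denom == 0) stop("perfect-force series is identically zero", call. = FALSE)
  sum(F_actual * F_FC) / denom
}

#' Pearson correlation between exerted and perfect force
#'
#' @param F_actual Measured lateral force series (N).
#' @param F_FC Full-compensatory force series (N).
#' @return Pearson r.
#' @export
correlation_coefficient <- function(F_actual, F_FC) {
  if (length(F_actual) != length(F_FC)) {
    stop("series must have equal length", call. = FALSE)
  }
  if (stats::var(F_actual) == 0 || stats::var(F_FC) == 0) {
    stop("correlation undefined for zero-variance series", call. = FALSE)
  }
  stats::cor(F_actual, F_FC)
}

#' Movement error
#'
#' Lateral displacement at the instant of maximum forward speed (earliest
#' index on ties), the per-trial movement-error measure.
#'
#' @param x Lateral displacement series (m).
#' @param vy Forward speed series (m/s), same length.
#' @return Displacement (m) at `which.max(vy)`.
#' @export
movement_error <- function(x, vy) {
  if (length(x) == 0L || length(x) != length(vy)) {
    stop("x and vy must be non-empty series of equal length", call. = FALSE)
  }
  x[which.max(vy)]
}

#' Adaptation analysis of the constant-perturbations phase
#'
#' For every error-clamp trial of the constant phase, computes the adaptation
#' coefficient and Pearson correlation between the recorded force profile and
#' the perfect force of that block's field amplitude, plus force-at-max-speed,
#' peak force, and movement error; then aggregates per condition amplitude.
#'
#' @param session A [run_subject()] result with clamp series stored
#'   (`keep_series` `"clamp"` or `"all"`).
#' @param measure `"wall"` (default): the physically measured channel-wall
#'   force, which carries a small compliance bias (the arm's own impedance
#'   absorbs ~5% of the expressed force with the default plant);
#'   `"commanded"`: the learner's expressed feedforward force
#'   `B_hat_used * vy`, free of channel compliance.
#' @param pooled If `TRUE`, concatenate all clamp profiles of a condition and
#'   fit one regression; default `FALSE` computes per-trial coefficients and
#'   averages them across the clamps of each condition.
#' @return A list with `per_trial` (tibble: one row per constant-phase clamp)
#'   and `per_condition` (tibble: condition `B`, `n_clamps`, mean `a`, `r`,
#'   `lf_max_speed`, `lf_peak`, `movement_error`).
#' @export
analyze_constant_phase <- function(session, measure = c("wall", "commanded"),
                                   pooled = FALSE) {
  measure <- match.arg(measure)
  sm <- session$summary
  blkB <- block_amplitudes(sm)
  idx <- which(sm$phase == "constant" & sm$trial_type == "error_clamp")
  if (length(idx) == 0L) stop("session has no constant-phase clamp trials",
                              call. = FALSE)
  rows <- lapply(idx, function(i) {
    rec <- session$records[[as.character(sm$index[i])]]
    if (is.null(rec)) {
      stop("clamp series not stored; rerun with keep_series = 'clamp'",
           call. = FALSE)
    }
    B_cond <- blkB[[as.character(sm$block_id[i])]]
    F_fc <- perfect_force(B_cond, rec$vy)
    F_act <- if (measure == "wall") rec$fx else rec$B_hat * rec$vy
    tibble::tibble(
      index = sm$index[i], block_id = sm$block_id[i], B = B_cond,
      a = adaptation_coefficient(F_act, F_fc),
      r = correlation_coefficient(F_act, F_fc),
      lf_max_speed = force_at_max_speed(F_act, rec$vy),
      lf_peak = F_act[which.max(abs(F_act))],
      movement_error = movement_error(rec$x, rec$vy)
    )
  })
  per_trial <- do.call(rbind, rows)

  conds <- sort(unique(per_trial$B))
  per_condition <- do.call(rbind, lapply(conds, function(b) {
    sub <- per_trial[per_trial$B == b, ]
    if (pooled) {
      recs <- lapply(sub$index, function(j) session$records[[as.character(j)]])
      F_fc <- unlist(lapply(recs, function(r) perfect_force(b, r$vy)))
      F_act <- unlist(lapply(recs, function(r) {
        if (measure == "wall") r$fx else r$B_hat * r$vy
      }))
      a <- adaptation_coefficient(F_act, F_fc)
      r <- correlation_coefficient(F_act, F_fc)
    } else {
      a <- mean(sub$a); r <- mean(sub$r)
    }
    tibble::tibble(B = b, n_clamps = nrow(sub), a = a, r = r,
                   lf_max_speed = mean(sub$lf_max_speed),
                   lf_peak = mean(sub$lf_peak),
                   movement_error = mean(sub$movement_error))
  }))
  list(per_trial = per_trial, per_condition = per_condition)
}
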