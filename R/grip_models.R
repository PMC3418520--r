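#' Grip series container
#'
#' Paired object-weight and grip-force sequences from a trial-by-trial lifting
#' protocol. Weight units are arbitrary (mass-proportional) and are absorbed
#' into the fitted variability weight.
#'
#' @param weights Object-weight series (arbitrary units).
#' @param gf Grip-force series (N), same length, length >= 4 (the models need
#'   a 3-trial history).
#' @return A list of class `grip_series` with `weights`, `gf`, `n`.
#' @export
grip_series <- function(weights, gf) {
  if (length(weights) != length(gf)) {
    stop("weights and gf must have equal length", call. = FALSE)
  }
  if (length(gf) < 4L) stop("grip series needs at least 4 trials", call. = FALSE)
  structure(list(weights = as.numeric(weights), gf = as.numeric(gf),
                 n = length(gf)), class = "grip_series")
}

#' Regression-model grip-force prediction
#'
#' Predicts the grip force of trial `n` from the previous three grip forces as
#' `w1 * mean(history) + w2 * extrapolation(history)`, where the extrapolation
#' term is the OLS line through the three history points evaluated at the next
#' index (one-step extrapolation).
#'
#' @param gf_history The previous 3 grip forces (N), oldest first.
#' @param w1 Weight on the history mean.
#' @param w2 Weight on the extrapolation term.
#' @return Predicted grip force (N).
#' @examples
#' regression_model_predict(c(2, 3, 4), 1, 0)  # 3 (pure mean)
#' regression_model_predict(c(2, 3, 4), 0, 1)  # 5 (pure extrapolation)
#' @export
regression_model_predict <- function(gf_history, w1, w2) {
  if (length(gf_history) != 3L) {
    stop("gf_history must hold exactly 3 grip forces", call. = FALSE)
  }
  w1 * mean(gf_history) + w2 * extrapolator_predict(gf_history)
}

#' Variance-model grip-force prediction
#'
#' Predicts the grip force of trial `n` as `w1 * mean(gf_history) +
#' w2 * sd(weight_history)`: the environmental-variability account, in which
#' grip force rises with the spread of recently encountered object weights
#' (a safety margin) rather than with their trend.
#'
#' @param gf_history The previous 3 grip forces (N), oldest first.
#' @param weight_history The previous 3 object weights (arbitrary units).
#' @param w1 Weight on the grip-force history mean.
#' @param w2 Weight on the weight variability term.
#' @param sd_denominator `"n-1"` (sample standard deviation, default) or
#'   `"n"`; the convention is absorbed into `w2` but documented and
#'   switchable.
#' @return Predicted grip force (N).
#' @examples
#' variance_model_predict(c(2, 3, 4), c(1, 2, 3), 0, 1)  # sd(1,2,3) = 1
#' @export
variance_model_predict <- function(gf_history, weight_history, w1, w2,
                                   sd_denominator = c("n-1", "n")) {
  if (length(gf_history) != 3L || length(weight_history) != 3L) {
    stop("both histories must hold exactly 3 trials", call. = FALSE)
  }
  sd_denominator <- match.arg(sd_denominator)
  s <- stats::sd(weight_history)
  if (sd_denominator == "n") s <- s * sqrt(2 / 3)
  w1 * mean(gf_history) + w2 * s
}

#' Variance accounted for
#'
#' `1 - var(observed - predicted) / var(observed)`: 1 for a perfect
#' prediction, 0 when the prediction explains no more variance than the
#' observed mean, negative when residuals vary more than the data.
#'
#' @param observed Observed series.
#' @param predicted Predicted series, same length.
#' @return VAF (dimensionless, <= 1).
#' @export
vaf <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("series must have equal length", call. = FALSE)
  }
  if (stats::var(observed) == 0) {
    stop("VAF undefined for zero-variance observations", call. = FALSE)
  }
  1 - stats::var(observed - predicted) / stats::var(observed)
}

.grip_regressors <- function(series, model, sd_denominator = "n-1") {
  n <- series$n
  fit_idx <- 4:n  # trials with a full 3-trial history
  x1 <- vapply(fit_idx, function(i) mean(series$gf[(i - 3):(i - 1)]), numeric(1))
  x2 <- switch(model,
    regression = vapply(fit_idx, function(i) {
      extrapolator_predict(series$gf[(i - 3):(i - 1)])
    }, numeric(1)),
    variance = vapply(fit_idx, function(i) {
      s <- stats::sd(series$weights[(i - 3):(i - 1)])
      if (sd_denominator == "n") s * sqrt(2 / 3) else s
    }, numeric(1)))
  list(idx = fit_idx, X = cbind(mean = x1, term = x2), y = series$gf[fit_idx])
}

#' Fit a two-parameter grip-force model
#'
#' Ordinary least squares of the observed grip forces on the model's two
#' regressors (history mean, plus either the one-step extrapolation of the
#' grip-force history or the standard deviation of the weight history), over
#' all trials with a full 3-trial history. No intercept is fitted by default
#' (the models have none); `intercept = TRUE` is available for sensitivity
#' analysis.
#'
#' @param series A [grip_series()].
#' @param model `"regression"` or `"variance"`.
#' @param intercept Add an intercept column?
#' @param sd_denominator Passed to the variance regressor; see
#'   [variance_model_predict()].
#' @return A list of class `grip_fit`: `model`, `w1`, `w2`, `intercept`
#'   (`NA` unless fitted), `vaf`, `r` (Pearson correlation between data and
#'   prediction), `fitted`, `residuals`, `n_fit`.
#' @export
fit_model <- function(series, model = c("regression", "variance"),
                      intercept = FALSE, sd_denominator = c("n-1", "n")) {
  model <- match.arg(model)
  sd_denominator <- match.arg(sd_denominator)
  reg <- .grip_regressors(series, model, sd_denominator)
  X <- reg$X
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  if (nrow(X) < ncol(X)) {
    stop("too few trials with a full history to fit ", ncol(X), " parameters",
         call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient design: the ", model,
         " model's regressors are collinear on this series", call. = FALSE)
  }
  coefs <- qr.coef(qrX, reg$y)
  fitted <- drop(X %*% coefs)
  resid <- reg$y - fitted
  structure(list(
    model = model,
    w1 = unname(coefs[["mean"]]),
    w2 = unname(coefs[["term"]]),
    intercept = if (intercept) unname(coefs[["(Intercept)"]]) else NA_real_,
    vaf = vaf(reg$y, fitted),
    r = stats::cor(reg$y, fitted),
    fitted = fitted, residuals = resid, n_fit = length(reg$y)
  ), class = "grip_fit")
}

#' @export
print.grip_fit <- function(x, ...) {
  cat(sprintf("grip_fit (%s model, %d fitted trials): w1 = %.3f, w2 = %.3f, VAF = %.3f, r = %.3f\n",
              x$model, x$n_fit, x$w1, x$w2, x$vaf, x$r))
  invisible(x)
}

#' Generate a synthetic grip series
#'
#' Stand-in for trial-by-trial lifting data (no such data are deposited): a
#' weight schedule is drawn, the first three grip forces track the first three
#' weights, and subsequent grip forces follow the chosen generative law plus
#' Gaussian noise.
#'
#' Weight schedules: `"random"` draws uniformly from 1-4 units in 0.5 steps;
#' `"increasing_series"` cycles 1, 2, 3, 4; `"mixed"` (default) embeds one
#' increasing 1-2-3-4 run per ~20 trials in a random background, emulating a
#' lifting protocol with implicit series.
#'
#' Generators: `"eq3"` (regression law: `w1 * mean + w2 * extrapolation` of
#' the previous three grip forces), `"eq4"` (variance law: `w1 * mean(gf) +
#' w2 * sd(weights)`), `"averager"` (grip tracks the mean of the previous
#' three weights).
#'
#' @param generator Generative law.
#' @param params List with `w1`, `w2` (ignored by `"averager"`). Defaults are
#'   the reported mean coefficients of each law (`eq3`: 0.66/0.32, `eq4`:
#'   0.81/0.25).
#' @param weight_schedule Weight-schedule pattern.
#' @param noise_sd Gaussian noise sd (N) added to each generated grip force.
#' @param n Series length.
#' @param seed Integer seed.
#' @return A [grip_series()].
#' @export
generate_grip_series <- function(generator = c("eq3", "eq4", "averager"),
                                 params = NULL,
                                 weight_schedule = c("mixed", "random",
                                                     "increasing_series"),
                                 noise_sd = 0.05, n = 200, seed = 1L) {
  generator <- match.arg(generator)
  weight_schedule <- match.arg(weight_schedule)
  if (is.null(params)) {
    params <- switch(generator,
                     eq3 = list(w1 = 0.66, w2 = 0.32),
                     eq4 = list(w1 = 0.81, w2 = 0.25),
                     averager = list())
  }
  if (n < 4L) stop("n must be at least 4", call. = FALSE)
  pool <- seq(1, 4, by = 0.5)
  withr::with_seed(as.integer(seed), {
    weights <- switch(weight_schedule,
      random = sample(pool, n, replace = TRUE),
      increasing_series = rep_len(1:4, n),
      mixed = {
        w <- sample(pool, n, replace = TRUE)
        n_runs <- max(0L, n %/% 20L)
        if (n_runs > 0L) {
          starts <- .place_blocks(n, n_runs, 4L, gap = 1L)
          for (s in starts) w[s:(s + 3L)] <- 1:4
        }
        w
      })
    gf <- numeric(n)
    gf[1:3] <- weights[1:3] + stats::rnorm(3, 0, noise_sd)
    for (i in 4:n) {
      hist_gf <- gf[(i - 3):(i - 1)]
      pred <- switch(generator,
        eq3 = regression_model_predict(hist_gf, params$w1, params$w2),
        eq4 = variance_model_predict(hist_gf, weights[(i - 3):(i - 1)],
                                     params$w1, params$w2),
        averager = mean(weights[(i - 3):(i - 1)]))
      gf[i] <- pred + stats::rnorm(1, 0, noise_sd)
    }
    grip_series(weights, gf)
  })
}

#' Write / read a grip series as CSV
#'
#' Two columns, `weight` (arbitrary units) and `grip_force` (N), with header.
#'
#' @param series A [grip_series()].
#' @param path CSV path.
#' @return `path` invisibly (write); a `grip_series` (read).
#' @export
write_grip_series <- function(series, path) {
  utils::write.csv(data.frame(weight = series$weights,
                              grip_force = series$gf),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grip_series
#' @export
read_grip_series <- function(path) {
  df <- utils::read.csv(path)
  grip_series(df$weight, df$grip_force)
}
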