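#' Post-sequence clamp forces of a session
#'
#' Extracts the force at maximum speed from exactly the error-clamp trials
#' that immediately follow an embedded increasing sequence, ordered by
#' sequence repetition.
#'
#' @param session A [run_subject()] result.
#' @return Numeric vector of forces (N), one per sequence-trailing clamp.
#' @export
extract_post_sequence_forces <- function(session) {
  sm <- session$summary
  sel <- sm[sm$trial_type == "error_clamp" & !is.na(sm$sequence_id), ]
  if (nrow(sel) == 0L) {
    stop("schedule contains no sequence-trailing clamp trials", call. = FALSE)
  }
  sel <- sel[order(sel$sequence_id), ]
  sel$fx_max_speed
}

#' Benchmark clamp forces from a constant-phase condition
#'
#' Forces at maximum speed from the error-clamp trials of the constant-phase
#' blocks whose field amplitude is `B` — e.g. `B = 2.5` (the sequence mean,
#' the "average" benchmark) or `B = 5` (the next term, the "next" benchmark).
#'
#' @param session A [run_subject()] result.
#' @param B Condition amplitude (Ns/m).
#' @return Numeric vector of forces (N), in trial order.
#' @export
benchmark_forces <- function(session, B) {
  sm <- session$summary
  blkB <- block_amplitudes(sm)
  blocks <- as.integer(names(blkB)[abs(blkB - B) < 1e-9])
  if (length(blocks) == 0L) {
    stop("no constant-phase blocks with B = ", B, call. = FALSE)
  }
  sel <- sm[sm$phase == "constant" & sm$trial_type == "error_clamp" &
              sm$block_id %in% blocks, ]
  sel$fx_max_speed
}

#' Two-sample t test
#'
#' Thin wrapper around [stats::t.test()] returning the statistic, degrees of
#' freedom and two-tailed p value. Unpaired tests pool variances (classical
#' two-sample t) unless `welch = TRUE`.
#'
#' @param x,y Numeric samples.
#' @param paired Paired test (requires equal lengths)?
#' @param welch Use the Welch correction for unpaired tests?
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, paired = FALSE, welch = FALSE) {
  if (paired && stats::sd(x - y) <= 1e-12 * max(abs(x - y), 1)) {
    # degenerate paired case: identical differences everywhere
    d <- mean(x - y)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = length(x) - 1, p = if (d == 0) 1 else 0))
  }
  tt <- stats::t.test(x, y, paired = paired,
                      var.equal = !paired && !welch,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Contrast post-sequence forces against the average and next benchmarks
#'
#' The headline inference: is the force expressed after an increasing 1-2-3-4
#' Ns/m sequence closer to what the same subjects express under a constant
#' field of the sequence mean (B = 2.5, the "average" benchmark) or of the
#' next term (B = 5, the "next" benchmark)? Differences are benchmark minus
#' post-sequence (positive when the benchmark exceeds the post-sequence
#' force); the two per-observation difference distributions are compared by a
#' t test (paired by default — both share the post-sequence observations, and
#' pairing yields df = n - 1, matching the df the observation-level pooling
#' implies).
#'
#' @param post_seq Forces (N) from sequence-trailing clamps.
#' @param bench_avg Forces (N) from the B = 2.5 constant-condition clamps.
#' @param bench_next Forces (N) from the B = 5 constant-condition clamps.
#' @param paired Pair the two difference distributions (default TRUE)?
#' @return A list of class `contrast_result`: `lf_post_sequence`,
#'   `lf_benchmark_avg`, `lf_benchmark_next`, `avg_diff`, `next_diff`,
#'   per-contrast one-sample tests (`t_avg`, `t_next`), and the
#'   average-vs-next comparison (`t_avg_vs_next`).
#' @export
contrast_differences <- function(post_seq, bench_avg, bench_next,
                                 paired = TRUE) {
  if (length(post_seq) == 0L || length(bench_avg) == 0L ||
      length(bench_next) == 0L) {
    stop("all three force samples must be non-empty", call. = FALSE)
  }
  if (length(bench_avg) != length(post_seq) ||
      length(bench_next) != length(post_seq)) {
    stop("benchmark and post-sequence samples must have equal length ",
         "(pair clamp observations in order within subject)", call. = FALSE)
  }
  d_avg <- bench_avg - post_seq
  d_next <- bench_next - post_seq
  one_sample <- function(d) {
    if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
      m <- mean(d)
      return(list(t = if (m == 0) 0 else sign(m) * Inf,
                  df = length(d) - 1, p = if (m == 0) 1 else 0))
    }
    tt <- stats::t.test(d, alternative = "two.sided")
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = unname(tt$p.value))
  }
  structure(list(
    lf_post_sequence = post_seq,
    lf_benchmark_avg = bench_avg,
    lf_benchmark_next = bench_next,
    avg_diff = mean(bench_avg) - mean(post_seq),
    next_diff = mean(bench_next) - mean(post_seq),
    t_avg = one_sample(d_avg),
    t_next = one_sample(d_next),
    t_avg_vs_next = two_sample_t(d_avg, d_next, paired = paired),
    # which benchmark is *closer*: compare the error magnitudes of the two
    # hypotheses (the signed difference is smaller for the average benchmark
    # for any learner whose post-sequence force is below the next benchmark)
    t_abs_avg_vs_next = two_sample_t(abs(d_avg), abs(d_next), paired = paired)
  ), class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast_result (n = %d clamp observations)\n",
              length(x$lf_post_sequence)))
  cat(sprintf("  post-sequence force: %.3f N | 'average' benchmark: %.3f N | 'next': %.3f N\n",
              mean(x$lf_post_sequence), mean(x$lf_benchmark_avg),
              mean(x$lf_benchmark_next)))
  cat(sprintf("  avg_diff = %.3f N, next_diff = %.3f N; avg vs next: t(%g) = %.2f, p = %.3g\n",
              x$avg_diff, x$next_diff, x$t_avg_vs_next$df, x$t_avg_vs_next$t,
              x$t_avg_vs_next$p))
  invisible(x)
}

#' Pool a cohort and run the average-vs-next contrast
#'
#' Concatenates, subject by subject, the post-sequence clamp forces and the
#' B = 2.5 / B = 5 benchmark clamp forces (paired in trial order within each
#' subject, 10 + 10 + 10 observations per subject with the default protocol)
#' and calls [contrast_differences()].
#'
#' @param sessions List of [run_subject()] results.
#' @param paired Passed to [contrast_differences()].
#' @return A `contrast_result`.
#' @export
cohort_contrast <- function(sessions, paired = TRUE) {
  post <- unlist(lapply(sessions, extract_post_sequence_forces))
  avg <- unlist(lapply(sessions, benchmark_forces, B = 2.5))
  nxt <- unlist(lapply(sessions, benchmark_forces, B = 5))
  contrast_differences(post, avg, nxt, paired = paired)
}

#' Post-sequence forces arranged by sequence repetition
#'
#' @param sessions List of [run_subject()] results.
#' @return Matrix, rows = subjects, columns = sequence repetitions.
#' @export
cohort_post_sequence_matrix <- function(sessions) {
  do.call(rbind, lapply(sessions, extract_post_sequence_forces))
}

#' One-way ANOVA across sequence repetitions
#'
#' Tests whether the post-sequence clamp force changes across the repetitions
#' of the embedded series (implicit learning of the series would produce a
#' repetition effect). Classical fixed-effects one-way ANOVA with equal
#' variances.
#'
#' @param groups Either a matrix (columns = groups/repetitions, rows =
#'   subjects) or a list of numeric vectors, each a group with >= 2
#'   observations.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
series_repetition_anova <- function(groups) {
  if (is.matrix(groups)) {
    groups <- lapply(seq_len(ncol(groups)), function(j) groups[, j])
  }
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    stop("need at least 2 groups with at least 2 observations each",
         call. = FALSE)
  }
  values <- unlist(groups)
  k <- length(groups)
  n_i <- lengths(groups)
  grand <- mean(values)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(unlist(Map(function(x, m) (x - m)^2, groups, means)))
  df1 <- k - 1L
  df2 <- length(values) - k
  # Degenerate conventions: no between-group variation -> F = 0 (p = 1), even
  # when the within-group variance is also zero; zero within-group variance
  # with real group differences -> F = Inf (p = 0).
  F_stat <- if (ssb == 0) 0 else (ssb / df1) / (ssw / df2)
  p <- stats::pf(F_stat, df1, df2, lower.tail = FALSE)
  list(F = F_stat, df1 = df1, df2 = df2, p = p)
}
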