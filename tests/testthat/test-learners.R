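test_that("averaging laws follow their closed forms", {
  # single-rate with full learning rate corrects in one trial
  s <- new_learner_state(params = list(law = "single_rate", eta = 1, A = 1))
  s <- averager_update(s, 3, "force_field")
  expect_equal(s$B_hat, 3)

  # FIR window over the embedded sequence predicts its mean
  s <- new_learner_state(params = list(law = "fir", k = 4))
  for (b in 1:4) s <- averager_update(s, b, "force_field")
  expect_equal(s$B_hat, 2.5)

  # single-rate over a constant field: B_hat(n) = 3 * (1 - 0.7^n)
  # (oracle: unrolled recursion)
  s <- new_learner_state(params = list(law = "single_rate", eta = 0.3, A = 1))
  for (n in 1:12) {
    s <- averager_update(s, 3, "force_field")
    expect_equal(s$B_hat, 3 * (1 - 0.7^n), tolerance = 1e-12)
  }

  # clamp trials freeze the state by default
  s2 <- averager_update(s, 99, "error_clamp")
  expect_equal(s2$B_hat, s$B_hat)
  expect_equal(s2$history, s$history)
  # ... unless a retention multiplier is set
  s3 <- new_learner_state(B_hat = 2, params = list(clamp_retention = 0.9))
  expect_equal(averager_update(s3, 99, "error_clamp")$B_hat, 1.8)
})

test_that("FIR averager stays within its window's range", {
  set.seed(31)
  s <- new_learner_state(params = list(law = "fir", k = 4))
  for (i in 1:200) {
    b <- sample(seq(1, 4, by = 0.5), 1)
    s <- averager_update(s, b, "force_field")
    expect_gte(s$B_hat, min(s$history))
    expect_lte(s$B_hat, max(s$history))
  }
})

test_that("linear extrapolation predicts the next term of a series", {
  expect_equal(extrapolator_predict(c(1, 2, 3, 4)), 5)
  expect_equal(extrapolator_predict(c(3, 3, 3)), 3)
  # arithmetic progression with step 2: OLS line continues it
  expect_equal(extrapolator_predict(c(1, 3, 5)), 7)
  # decreasing series extrapolates downward
  expect_equal(extrapolator_predict(c(4, 3, 2, 1)), 0)
  expect_error(extrapolator_predict(c(2)), "at least 2")
})

test_that("run_subject rejects unknown learners, listing the registry", {
  expect_error(run_subject(small_schedule(), "kalman"),
               "averager_fir.*averager_single_rate.*extrapolator")
  expect_setequal(learner_registry(),
                  c("averager_fir", "averager_single_rate", "extrapolator"))
})

test_that("noiseless learners express their hypothesis in post-sequence clamps", {
  v_peak <- max(default_profile()$vy)

  avg <- noiseless_subject("averager_fir")
  ps_avg <- extract_post_sequence_forces(avg)
  expect_length(ps_avg, 10L)
  # FIR-4 window holds exactly 1,2,3,4 after each sequence: gain 2.5;
  # the channel wall absorbs ~all of it (within 5%)
  expect_true(all(abs(ps_avg / (2.5 * v_peak) - 1) < 0.05))
  sm <- avg$summary
  expect_equal(sm$B_hat[sm$trial_type == "error_clamp" & !is.na(sm$sequence_id)],
               rep(2.5, 10))

  ext <- noiseless_subject("extrapolator")
  ps_ext <- extract_post_sequence_forces(ext)
  expect_true(all(abs(ps_ext / (5 * v_peak) - 1) < 0.05))
  sm_e <- ext$summary
  expect_equal(sm_e$B_hat[sm_e$trial_type == "error_clamp" & !is.na(sm_e$sequence_id)],
               rep(5, 10))

  # hypothesis separation: gap in expressed gains is 2.5 Ns/m >= 2
  gap <- mean(sm_e$B_hat[sm_e$trial_type == "error_clamp" & !is.na(sm_e$sequence_id)]) -
    mean(sm$B_hat[sm$trial_type == "error_clamp" & !is.na(sm$sequence_id)])
  expect_gte(gap, 2)
})

test_that("sessions are deterministic per seed and serialize identically", {
  s1 <- run_subject(small_schedule(), "averager_fir", seed = 9)
  s2 <- run_subject(small_schedule(), "averager_fir", seed = 9)
  d1 <- tempfile(); d2 <- tempfile()
  write_session(s1, d1); write_session(s2, d2)
  for (f in c("summary.csv", "records.csv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  s3 <- run_subject(small_schedule(), "averager_fir", seed = 10)
  expect_false(identical(s1$summary$B_hat_used, s3$summary$B_hat_used))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("session round-trips through CSV/JSON and supports analysis", {
  s <- run_subject(small_schedule(), "averager_fir", seed = 3)
  d <- tempfile()
  write_session(s, d)
  back <- read_session(d)
  expect_equal(as.data.frame(back$summary), as.data.frame(s$summary),
               tolerance = 1e-12)
  expect_setequal(names(back$records), names(s$records))
  rec <- s$records[[1]]; brec <- back$records[[names(s$records)[1]]]
  expect_equal(brec$fx, rec$fx, tolerance = 1e-12)
  # analysis surface works on the round-tripped session
  a1 <- analyze_constant_phase(s)$per_condition
  a2 <- analyze_constant_phase(back)$per_condition
  expect_equal(as.data.frame(a2), as.data.frame(a1), tolerance = 1e-9)
  unlink(d, recursive = TRUE)
})

test_that("fast unit-response path equals direct RK4 simulation", {
  sch <- small_schedule()
  cfg <- sim_config()
  s <- run_subject(sch, list(name = "averager_fir", params = list(noise_sd = 0)),
                   config = cfg, seed = 2, keep_series = "all")
  p <- s$profile
  sm <- s$summary
  # check a handful of trials of each type against the direct simulators
  for (i in c(1, 12, 25, 40, 60, 90, 120)) {
    rec <- s$records[[as.character(sm$index[i])]]
    if (sm$trial_type[i] == "error_clamp") {
      direct <- simulate_clamp_trial(sm$B_hat_used[i], p, cfg$plant)
    } else {
      B <- ifelse(is.na(sm$B[i]), 0, sm$B[i])
      direct <- simulate_field_trial(sm$B_hat_used[i], B, p, cfg$plant)
    }
    expect_lt(max(abs(rec$x - direct$x)), 1e-8)
    expect_lt(max(abs(rec$fx - direct$fx)), 1e-8)
  }
})

test_that("baseline zeros enter the FIR average (seeded window or experienced nulls)", {
  # with no baseline phase, the seeding flag is what injects the zero prior
  cfg <- default_protocol_config(
    n_baseline = 0L, n_random = 40L, n_constant = 80L, block_size = 20L,
    constant_amplitudes = c(2.5, 5), n_sequences = 2L,
    clamp_fraction_random = 0.10, clamps_per_block = 3L)
  sch <- build_schedule(cfg, seed = 7)
  seeded <- run_subject(sch, list(name = "averager_fir",
                                  params = list(noise_sd = 0)), seed = 1,
                        keep_series = "none")
  unseeded <- run_subject(sch, list(name = "averager_fir",
                                    params = list(noise_sd = 0,
                                                  baseline_seeding = FALSE)),
                          seed = 1, keep_series = "none")
  sm_s <- seeded$summary; sm_u <- unseeded$summary
  forces <- which(sm_s$trial_type == "force_field")
  second_force <- forces[2]
  # after one force trial: the seeded average dilutes it across the zero
  # window, the unseeded average equals the experienced amplitude itself
  expect_lt(sm_s$B_hat[second_force], sm_u$B_hat[second_force])

  # with a null-field baseline, experienced zeros fill the window anyway and
  # the flag no longer matters by the end of the baseline
  sch_b <- small_schedule()
  s_b <- run_subject(sch_b, list(name = "averager_fir",
                                 params = list(noise_sd = 0)), seed = 1,
                     keep_series = "none")
  u_b <- run_subject(sch_b, list(name = "averager_fir",
                                 params = list(noise_sd = 0,
                                               baseline_seeding = FALSE)),
                     seed = 1, keep_series = "none")
  last_base <- max(which(s_b$summary$phase == "baseline"))
  expect_equal(s_b$summary$B_hat[last_base], u_b$summary$B_hat[last_base])
})
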