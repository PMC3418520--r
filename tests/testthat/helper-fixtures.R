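# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_schedule <- function() cached("schedule", build_schedule(seed = 42))

default_profile <- function() cached("profile", minjerk_profile())

# A small but structurally complete protocol for fast simulation tests:
# 2 embedded sequences, 2 constant conditions (2.5 and 5 Ns/m) x 2 blocks.
small_config <- function() {
  default_protocol_config(
    n_baseline = 10L, n_random = 40L, n_constant = 80L, block_size = 20L,
    constant_amplitudes = c(2.5, 5), n_sequences = 2L,
    clamp_fraction_random = 0.10, clamps_per_block = 3L
  )
}

small_schedule <- function() cached("small_schedule",
                                    build_schedule(small_config(), seed = 7))

# Noiseless single subjects on the full default schedule.
noiseless_subject <- function(learner_name) {
  cached(paste0("noiseless_", learner_name), {
    run_subject(default_schedule(),
                list(name = learner_name, params = list(noise_sd = 0)),
                seed = 5)
  })
}

# Cohorts (10 subjects, default 5% execution noise) on the default schedule.
default_cohort <- function(learner_name) {
  cached(paste0("cohort_", learner_name), {
    run_cohort(default_schedule(), learner_name, n_subjects = 10, seed = 100,
               keep_series = "none")
  })
}

trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
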