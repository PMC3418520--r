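---
title: "Models and methods: trial-by-trial adaptation to sequence force fields"
author: "reachadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: trial-by-trial adaptation to sequence force fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachadapt)
```

## The scientific question

When a reaching movement is repeatedly perturbed by a viscous curl force
field whose amplitude grows in a short predictable series — 1, 2, 3, 4 Ns/m —
what does the motor system expect on the next trial? Two hypotheses make
sharply different predictions:

* **averaging the past**: the feedforward compensation approximates the mean
  of the recent perturbations, 2.5 Ns/m;
* **extrapolating the future**: the compensation anticipates the next term of
  the series, 5 Ns/m.

The package implements the full in-silico apparatus needed to pose and test
this contrast: the three-phase experimental protocol, a reach/channel
simulator, synthetic learners embodying each hypothesis, the force-profile
measures used to read out adaptation, the average-vs-next inference, and the
two trial-by-trial grip-force models used to discuss why lifting tasks can
show the opposite (future-predicting) behaviour.

Because no subject data are deposited for this paradigm, everything here runs
on synthetic cohorts. A green test therefore establishes that the *pipeline*
reproduces the qualitative logic of the paradigm under its stated
assumptions — not that any human cohort behaves this way.

## The protocol

`build_schedule()` generates a 780-trial session in three phases:

1. **baseline** — 100 null-field trials (`B = 0`);
2. **random perturbations** — 200 trials with field amplitudes drawn
   uniformly from \{1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0\} Ns/m, with 10
   embedded increasing sequences (1, 2, 3, 4 Ns/m on consecutive trials, each
   followed immediately by an error-clamp trial), and 10% of the phase being
   error clamps in total;
3. **constant perturbations** — 12 blocks of 40 trials, one amplitude per
   block, each of \{1, 2, 2.5, 3, 4, 5\} Ns/m appearing in exactly two
   blocks, with 5 error clamps randomly interspersed per block (12.5%), never
   on a block's first trial.

Since only 10 of the 20 random-phase clamps can trail the 10 sequences, the
remaining 10 are placed uniformly among background positions, never adjacent
to a sequence block, so that a sequence's trailing clamp is unambiguous. The
uniform-amplitude statistics apply to the background only; the embedded
sequences are excluded from them. The constant-phase block *order* is a
seed-determined permutation, fixed across the subjects of a cohort (the
protocol presents the same order to every subject) and overridable via
`block_order` in the config. All trial indices are 0-based in serialized
files.

Gaps between embedded sequences are drawn as a multinomial split of the free
slack, which is deterministic per seed and guarantees non-overlap with at
least one background trial between sequences. This does not sample the
placement set perfectly uniformly; nothing downstream depends on placement
uniformity.

## Reach and channel simulation

Reaches are along +y over `distance` = 0.13 m in `duration` = 0.45 s at
200 Hz — values chosen (and clearly labelled as stand-ins, since the paradigm
does not fix them) so that peak speed is 1.875·D/T ≈ 0.54 m/s, inside the
observed 53.1–57.8 cm/s range. The forward speed is the minimum-jerk
polynomial; the sampled profile is rescaled by ~1 part in 5·10⁸ so that its
trapezoidal integral equals the reach distance exactly.

The lateral (x) plant is a deliberately simple linear stand-in: a 1 kg point
mass with arm impedance 50 N/m and 10 Ns/m. On field trials the drive is the
compensation mismatch `(B − B_hat)·vy(t)`; a perfectly compensated field
produces zero lateral error, and an uncompensated rightward field produces a
rightward error peaking after peak speed. On clamp trials the channel adds
the spring–damper 1000 N/m / 50 Ns/m, and the recorded force is the force
pressed into the channel wall, `k_ch·x + b_ch·ẋ`.

Integration is fixed-step RK4 at the sampling interval with optional
sub-stepping; the integrator refuses plants whose fastest eigenvalue exceeds
the RK4 stability margin (|λ|·h > 2.5) and says how to fix it. Because the
plant is linear and time-invariant, `run_subject()` scales unit responses
instead of re-integrating every trial; a test verifies this equals direct
RK4 simulation to 1e-8 (the superposition oracle).

Two numerical consequences are worth knowing:

* **channel compliance bias**: the wall absorbs `k_ch/(k_ch + k_arm)` ≈ 95%
  of the expressed force quasi-statically (measured at peak speed: ~98%), so
  wall-force-based adaptation coefficients saturate slightly below 1 even for
  a perfect learner. `analyze_constant_phase(measure = "commanded")` switches
  to the noise-free expressed force `B_hat·vy`, for which a perfect learner
  reaches a = r = 1 at machine precision. The default (`"wall"`) keeps the
  bias: it is what a force sensor sees, and it mirrors the sub-unity
  coefficients real channel experiments report.
* **clamp residual error**: ~1 mm at `B_hat` = 2.5 Ns/m, matching the order
  of magnitude of real channel trials (< 1.3 mm), and at least 10× smaller
  than matched uncompensated field errors.

## Synthetic learners

Both learners update once per trial from the *experienced* amplitude: the
scheduled `B` on force trials and 0 on null trials. Error-clamp trials
present approximately zero error, so by default they freeze the state
(`clamp_retention = 1`; values < 1 decay the gain instead) — freezing
isolates the clamps' measurement role.

* `averager_fir`: `B_hat` is the mean of the last `k` = 4 experienced
  amplitudes. After a 1-2-3-4 sequence its window holds exactly the sequence,
  so it expresses 2.5 Ns/m on the trailing clamp.
* `averager_single_rate`: `B_hat ← A·B_hat + η·(B − B_hat)` with retention
  `A` = 1 and learning rate `η` = 0.3 by default — the classical single-rate
  state-space learner, included as the smoother instantiation of the same
  averaging hypothesis.
* `extrapolator`: OLS line through the window's (index, amplitude) pairs
  evaluated one step ahead; after 1-2-3-4 it expresses 5 Ns/m.

With `baseline_seeding = TRUE` (default) the FIR/extrapolator window starts
filled with zeros. In the full protocol this is nearly immaterial — the
baseline nulls push experienced zeros into the window anyway — but it defines
the prior for schedules that begin abruptly, and it is the mechanism by which
an averaging subject can under-predict the sequence mean (zeros from the
baseline dilute the average), as observed in the human data.

Execution noise is multiplicative on the expressed gain,
`B_hat_used = B_hat·(1 + ε)`, `ε ~ N(0, 0.05)`: motor noise scales with
signal strength, and 5% keeps post-sequence force SDs in a realistic few
percent of the mean. The two shipped learners are hypothesis instantiations,
not claims about subjects; the registry is extensible.

## Force-profile measures

All adaptation readouts come from clamp trials. `force_at_max_speed()` takes
the force sample at peak speed (earliest index on ties); since fields are
velocity-proportional, it coincides with peak force for an adapted learner
(and the two measures agree within 5% on simulated clamps).
`adaptation_coefficient()` is the through-origin regression slope
⟨F_actual, F_FC⟩/⟨F_FC, F_FC⟩ against the perfect force `B·vy` — the model
`F_actual = a·F_FC` has no offset, so no intercept is fitted (the
through-origin reading is adopted and flagged; nothing in the paradigm
suggests an intercept). `correlation_coefficient()` is the plain Pearson r.
Per-condition values are computed per clamp and averaged across the ten
clamps of a condition (`pooled = TRUE` concatenates profiles into a single
regression instead). No baseline force subtraction is applied.

## The average-vs-next contrast

`cohort_contrast()` pools, per subject, the 10 post-sequence clamp forces,
the 10 clamp forces of the `B` = 2.5 constant condition ("average"
benchmark), and the 10 of `B` = 5 ("next" benchmark), pairing observations in
trial order within subject (100 triplets for a 10-subject cohort). The two
difference distributions, `d_avg = bench_avg − post_seq` and
`d_next = bench_next − post_seq`, are compared by a **paired** t test by
default: both share the post-sequence observations, and pairing yields
df = n − 1 = 99, the degrees of freedom that observation-level pooling
implies. An unpaired option is provided.

One definitional subtlety: with differences defined as benchmark minus
post-sequence, `avg_diff < next_diff` holds for *any* learner, because the
2.5 benchmark always sits below the 5 benchmark. What dissociates the
hypotheses is which benchmark is **closer** — the magnitudes of the
differences. The contrast result therefore reports both the signed
comparison (`t_avg_vs_next`, the form used for human cohorts, where
both differences come out positive) and the magnitude comparison
(`t_abs_avg_vs_next`), and the dissociation tests use the magnitudes: an
averaging cohort has |avg_diff| ≪ |next_diff|, an extrapolating cohort the
reverse, each at p < 0.001 with 10 subjects and default noise.

`series_repetition_anova()` (classical fixed-effects one-way ANOVA,
hand-assembled sums of squares with `stats::pf`, cross-checked against
`anova(lm(...))` in the tests) asks whether post-sequence forces drift across
the 10 sequence repetitions — implicit learning of the series would produce
a repetition effect. A stationary learner shows none (p > 0.05 in ≥ 90% of
seeded replicates); its p-values are calibrated uniform under the null.
Degenerate inputs follow explicit conventions: zero between-group variation
gives F = 0, p = 1; zero within-group variance with real group differences
gives F = ∞, p = 0. No multiple-testing correction is applied anywhere, as
is conventional for this paradigm's small set of planned contrasts; this is
deliberate and documented.

## Grip-force models

For the lifting-task discussion, two two-parameter models predict the grip
force of trial n from a 3-trial history:

* **regression model**: `GF̂[n] = w1·mean(GF[n−3:n−1]) +
  w2·extrap(GF[n−3:n−1])`, the extrapolation being the OLS line through the
  three points evaluated at n;
* **variance model**: `GF̂[n] = w1·mean(GF[n−3:n−1]) +
  w2·sd(Weight[n−3:n−1])`.

`sd` uses the sample (n−1) denominator by default, switchable — the
convention is absorbed into `w2` either way. Weight units are arbitrary and
likewise absorbed into `w2`. Both models are fitted by two-regressor OLS
without intercept over trials 4…n; the first three trials (incomplete
history) are excluded, collinear designs raise an explicit rank-deficiency
error rather than being silently resolved, and fits are compared by VAF
(`1 − var(residual)/var(observed)`) and Pearson r. Since both models have
exactly two parameters, VAF comparison needs no complexity correction.

`generate_grip_series()` provides synthetic series for parameter recovery:
noiseless series generated by either law are refitted to their exact
coefficients (1e-10), and at noise sd 0.05 N, n = 200, the mean recovered
`w1` is within ±0.02 of truth over 500 seeds. The default coefficients are
the reported means of each law (0.66/0.32 and 0.81/0.25). One honest
limitation: the regression law is purely self-referential (weights never
enter it), so a noiseless series decays toward zero and the default noisy
series is a near-unit-root AR(3) whose fitted VAF (~0.99) is far above the
~0.6 seen in human lifting data — human grip forces carry load-tracking
structure this generator does not model. The synthetic VAF is therefore a
closure check, not a reproduction of human fit quality; the variance
law, which weights do enter, lands nearer (~0.95).

## What the synthetic world does not establish

The simulator omits two-joint biomechanics, muscle dynamics, gravity (the
vertical/horizontal distinction is a label only — the paradigm found the two
equivalent), visual feedback, reaction times, savings/interference, and
two-rate learning. The human cohort's absolute numbers (forces of
0.69–1.59 N, differences of 0.12/0.69 N, adaptation coefficients 0.53–1.03)
depend on the unavailable subject data and are **not** reproduction targets;
the pipeline reproduces the protocol exactly, the equations analytically,
and the inference logic qualitatively.
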