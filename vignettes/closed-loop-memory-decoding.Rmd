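---
title: "Closed-loop memory-state decoding: models, generators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop memory-state decoding: models, generators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memloop)
```

`memloop` simulates and analyses closed-loop stimulation experiments in
delayed free recall: a per-subject classifier decodes the probability of
later recall from spectral features of intracranial EEG during each word's
encoding period, stimulation is triggered when that probability falls below
a threshold on designated lists, and stimulation's effect on recall and on
the decoded brain state is estimated with mixed-effects models. This
vignette documents the models, the synthetic-data generator that stands in
for human recordings, the numerical choices, and the limits of what the
package's tests can show.

## The task and its schedule

A session is one practice list plus 25 task lists of 12 words; each word is
shown for 1,600 ms with a 750–1,000 ms jittered inter-stimulus interval,
followed per list by a 20 s arithmetic distractor and a 30 s free-recall
period. In closed-loop sessions, lists 1–3 are unstimulated baseline lists;
lists 4–25 are 11 Stim and 11 NoStim lists in random interleave. These
counts are invariants of `make_schedule()` and hold for every seed.
Record-only sessions — the classifier's training data — are 25 unstimulated
lists.

## The signal chain

Raw multichannel signal is processed exactly as a practitioner would
process clinical iEEG:

1. **Line-noise filter.** A fourth-order Butterworth band-stop, 5 Hz wide
   and centred on 60 Hz (edges 57.5–62.5 Hz), applied forward–backward.
   Zero-phase filtering avoids epoch-relative latency shifts at the price
   of doubling the effective order; harmonics of 60 Hz are left alone
   (a single centred stop band is applied, nothing else).
2. **Bipolar montage.** Virtual channels are differences of immediately
   adjacent contacts on one probe; a k-contact probe yields k − 1 virtual
   channels. Common-mode signal (reference drift, shared line noise)
   cancels identically.
3. **Spectral power.** Complex Morlet wavelets, wave number 5, at 8
   frequencies geometrically spaced with endpoints exactly 3 and 180 Hz
   (ratio `60^(1/7)`; ≈ 3.0, 5.4, 9.7, 17.3, 31.1, 55.9, 100.3, 180.0 Hz).
   Power is measured over the half-open `[0, 1366)` ms epoch from word
   onset, with 1,365 ms mirrored buffers prepended and appended before
   convolution and discarded after, then natural-log-transformed and
   averaged over time. The log base is a free choice — any base rescales
   all features uniformly and is absorbed by z-scoring — so the natural log
   is used. Epoch boundaries are half-open in sample units to avoid
   double-counting boundary samples.
4. **Normalization.** One z-score per (virtual channel × frequency) column.
   Within-session normalization (training data) makes each column mean 0,
   SD 1 exactly over the session's word events. In the closed loop,
   normalization statistics are fit on the practice + baseline lists and
   applied verbatim to incoming events; they are refit after each completed
   NoStim list on all unstimulated-list events so far. Stim-list events
   never enter the normalization set, on the reading that
   stimulation-contaminated physiology should not define the reference
   distribution. The per-column granularity is a documented interpretation:
   normalizing "within frequency band" leaves the channel dimension open,
   and feature-wise standardization is what the penalized classifier needs.

## The decoder

The recall classifier is L2-penalized logistic regression in the LIBLINEAR
convention: minimize `½‖W‖² + C Σ c_y log(1 + exp(−y(xW + b)))` with the
intercept unpenalized and class weights `c_k = n/(2 n_k)`, so both classes
contribute equally despite the ~26–30% recall base rate. The penalty
constant defaults to `C = 2.4e-4`. The trainer is a deterministic BFGS
minimization with analytic gradients from a zero start; the tests verify it
against an independent derivative-free optimization of the same objective.

Classifier AUC is the tie-aware Mann–Whitney statistic. Evaluation uses
stratified 5-fold cross-validation with deterministic round-robin fold
assignment: with ~100 features even a heavily shrunk model ranks its own
training rows far above chance (AUC is scale-invariant), so training-set
AUC cannot sit at 0.5 under label permutation, whereas the cross-validated
permutation null is centred at 0.5 as it must be. The permutation test
shuffles labels, refits the full pipeline (same C, same class-weight rule)
and recomputes cross-validated AUC `n_perm` times;
`p = (1 + #{null ≥ observed}) / (n_perm + 1)`.

Feature attributions use the forward model `A = Σ_x W / σ²_ŷ`, with the
feature covariance `Σ_x` and the variance of the logit-transformed outputs
both taken over the events supplied for attribution, using the biased (1/n)
estimator — the ratio is invariant to that shared choice. Whether the
original analysis computed `σ²_ŷ` on training or evaluation events is not
stated anywhere authoritative; this package uses the attribution events and
flags that as an interpretation. Group maps average per-subject
attributions within region × frequency cells and attach one-sample t
statistics across subjects.

## The closed loop

During simulated closed-loop sessions each task-list event is normalized
with the current statistics version and decoded. On Stim lists a decoded
probability **strictly below** the threshold (default 0.5) triggers
stimulation — exactly 0.5 does not, following the "fell below" reading. On
NoStim lists the same computation runs with stimulation disabled, and
below-threshold words are flagged as matched controls. Target selection
scores each pair's high-frequency (≥ 70 Hz) SME with a two-sample t
statistic and picks the maximum among lateral-temporal pairs when any
exist, otherwise the global maximum; ties break to the lowest pair index.
Stimulation parameters are the pre-test argmax of the classifier-output
change within the safety amplitude cap (1.5 mA depth / 3.5 mA surface),
ties resolved toward lower amplitude then lower frequency.

Flanking sets contain the immediate forward and reverse neighbours of
unrecalled stimulated (or matched) words, provided both neighbours are
themselves unstimulated (or, on NoStim lists, above threshold); a flanking
row is never a stimulated word.

## The synthetic generator

The generator defines the study conditions under which everything is
tested. Two shipped profiles mirror the two study arms:

| parameter | lateral_temporal | non_lateral |
|---|---|---|
| marginal record-only recall | 0.261 | 0.298 |
| stimulation odds ratio | 1.18 | 0.87 |
| flanking log-odds | 0.20 | 0 |
| post-stimulation decoded-probability shift | +0.01 | 0 |

Recall is drawn from a logistic model with crossed subject and site random
effects — intercept SD 0.30 (subject) and 0.15 (site), condition-slope SD
0.15 each, values chosen so that the trial-level standard error at the
study's design scale (~29 sites × ~130 analyzed words) reproduces the
reported uncertainty of the stimulation effect (`t ≈ 2` at OR 1.18). The
generating model deliberately mirrors the fitted mixed model so that
parameter recovery is a well-posed estimand. `baseline_recall_prob` is the
**marginal** rate: the paper-style group grand mean. The generating
intercept therefore absorbs the logit-normal marginalization shift
(solved numerically; under the log link the correction is `−σ²/2`).
Conditional effects (the OR, RR, flanking and Δ parameters) are untouched
by this correction.

Each word stores its latent uniform draw, so when the closed-loop simulator
triggers stimulation the word's recall is re-derived from the same latent
variable under the stimulated log-odds: a positive effect can flip words
from forgotten to recalled but never the reverse, which keeps the
trial-level coupling between trigger decisions and outcomes coherent.

Spectral features are unit-variance Gaussian per (pair × frequency) column
with a class-conditional shift: recalled words sit `loading × sme_effect`
standardized units above forgotten words at the two highest frequencies
and the same amount below at the three lowest, matching the
high-up/low-down SME topography. Per-pair loadings (uniform on 0.3–1) make
electrodes differ in informativeness, which is what target selection needs.
The default `sme_effect = 0.125` was calibrated once, before freezing, so
that classifiers trained on 3 record-only sessions reach a mean held-out
NoStim AUC of ≈ 0.61 across 25 subject-sites — the generalization level
observed in closed-loop recordings — and was not revisited afterwards.

The post-stimulation effect is parameterized on the decoded-probability
scale (`stim_feature_delta`): for the word following a stimulated word the
feature vector is shifted along the trained classifier's favorable
direction by the amount that moves its decoded probability by exactly
`stim_feature_delta`, back-solved through that subject's model. The effect
is parameterized this way because the quantity of scientific interest — and
the quantity the Δ-classifier model estimates — lives on the classifier
output scale, not on raw power.

Raw signal adds, per monopolar channel, 1/f² background noise (spectral
shaping), a shared reference drift, 60 Hz line noise with a large common
and a small per-channel component, and event-locked Hann-windowed
oscillatory bursts at the informative frequencies whose log-amplitude is
modulated by later recall (gain 0.05 per unit loading, set so that the full
raw pipeline yields held-out AUC ≈ 0.65 on condensed two-session fixtures —
a realistic single-subject level). Bursts are injected into the anode
contact of each pair so they survive bipolar re-referencing.

What the generator does **not** emulate: recall dynamics (output order,
inter-response times), word semantics, epileptiform artifacts, electrode
drift across sessions, heterogeneous sampling rates, or any real anatomy
(regions are synthetic labels). Passing tests therefore demonstrate that
the pipeline recovers the effects it assumes under its own statistical
structure — not that the effects exist in, or would be recovered from, any
particular real recording.

## Effect models

The primary model is a binomial logistic mixed model of trial-level recall
on condition (stimulated vs matched control), with random intercepts and
condition slopes for subject and for stimulation site as crossed grouping
factors (three synthetic subjects carry two sites, as in the study design).
The group analysis adds group and condition × group fixed effects.
Estimation uses `lme4::glmer` with `nAGQ = 0` (penalized iteratively
reweighted least squares, no adaptive-quadrature correction) as the
documented approximation to the marginal likelihood: at the study's design
scale it showed equal-or-better null calibration than the Laplace fit in
this package's replicate experiments (type-I ≈ 0.07 vs 0.10 at α = 0.05)
and is severalfold faster. Random-effect variances in these designs are
frequently estimated at the boundary (singular fits); estimates carry a
flag when that happens, and the collapse-to-GLM property (a zero-variance
fit equals ordinary logistic regression) is tested explicitly.

t statistics are reported with residual degrees of freedom (n − p), the
convention that matches the magnitudes reported for this design family
(e.g. t(3,828) for ~3,830 analyzed words); the choice is held constant
across all models. All tests are two-tailed at α = 0.05; no
multiple-testing correction is applied in the primary effect models.

The relative-risk model is a binomial GLM with log link on the same rows,
reported as `100 × (RR − 1)` percent. When the log-link fit diverges
(fitted probabilities at the boundary), the modified-Poisson surrogate
(Poisson regression with HC0 sandwich variance) is used and flagged in the
output. The Δ-classifier model is a linear mixed model of consecutive-word
decoded-probability changes (word after a stimulated/matched word minus the
word itself) on condition, with the same random-effects structure.

## Numerical choices and degenerate inputs

* Geometric frequency grid endpoints are exact (3 and 180 Hz); the wavelet
  peak-frequency mapping is verified against an FFT oracle.
* Mirror padding uses the epoch's own samples reflected at both ends; for
  a stationary sinusoid at a centre frequency the mean log power equals
  the closed-form `log(A²/4)` within 5%, confirming no edge bias.
* Zero-SD feature columns, single-class label vectors, constant decision
  scores, epochs outside the recording, stimulation assignments on
  non-Stim lists, and missing stage artifacts all raise typed errors
  naming the offending object.
* All generators are bit-reproducible under fixed seeds; child seeds
  derive from one master seed, and the staged pipeline writes byte-stable
  CSV/JSON artifacts with a manifest of digests.
* Time is milliseconds from word onset, epochs are half-open, and CSV
  files use '.' decimals in UTF-8 with a documented column order.

## Problem sizes used in the shipped checks

Recovery experiments run at the study's design scale: ~29 subject-sites ×
~130 analyzed words (lateral-temporal OR and percent change), ~11 sites
(non-lateral OR), ~18 sites × ~78 consecutive-word pairs (Δ-classifier),
with 100 seeded replicates in `scripts/acceptance.R` and 40 in the test
suite; permutation tests use 200 permutations at 300 events; the held-out
generalization check trains 25 synthetic subject-sites on 3 record-only
sessions each. Raw-signal checks use condensed sessions (10 of 25 lists)
— the spectral pipeline is linear per event, so list count affects only
Monte-Carlo precision, not the estimand.

## Known limitations

* The EDF writer/reader is a minimal 16-bit subset (one-second records,
  integer physical ranges) sufficient for lossless round-trips of
  synthetic recordings; it is not a general-purpose EDF implementation.
* The log-binomial model fits condition only; covariate-adjusted
  relative risks would need the same care with link-boundary divergence.
* Whether the original closed-loop system refit normalization statistics
  on all unstimulated events or NoStim-list events only is unknowable from
  the public record; the conservative reading (exclude Stim lists) is
  implemented and documented above.
* With `nAGQ = 0`, random-effect variance estimates are approximate; fixed
  effects and their recovery behaviour — the quantities this package
  reports — were verified by simulation, but the variance components
  themselves should not be over-interpreted.
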