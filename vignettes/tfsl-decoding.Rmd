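---
title: "Decoding binary choices from time-frequency resolved synchronization likelihood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding binary choices from time-frequency resolved synchronization likelihood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Can a binary preference decision be predicted trial by trial from the EEG
recorded *before* the decision is reported? The approach implemented here
treats inter-regional neural synchronization as the carrier of the decision
signal: for every trial it extracts a time-frequency resolved
synchronization likelihood (TFSL) pattern from 64-channel EEG, ranks those
patterns by univariate class discriminability, greedily selects a compact
feature subset, and classifies single trials with a small feedforward
network. Two model scopes are evaluated: a combined global model (CGM) that
pools all participants into one classifier, and a personalized average
model (PAM) that fits one classifier per participant and averages the
per-participant accuracies.

No public recording accompanies the original study, so the package ships a
first-class synthetic generator whose ground truth is known by
construction; every stage of the pipeline is validated against it.

# Synchronization likelihood

Synchronization likelihood (SL) measures generalized synchronization
between two signals through recurrences of embedded states. For a channel
$x$ and band-specific lag $L$ and dimension $m$, the delay vector at sample
$t$ is

$$X_t = (x_t, x_{t+L}, \dots, x_{t+(m-1)L}).$$

At an anchor (reference) time $a$, the critical distance
$\varepsilon_x(a)$ is the smallest radius containing a fixed fraction
$p_{\mathrm{ref}}$ of the candidate vectors (the
$\lceil p_{\mathrm{ref}} N \rceil$-th order statistic of the Euclidean
distances, after Theiler exclusion of the $(m-1)L$ samples around the
anchor). With recurrence sets $R_x$ and $R_y$ built at the same anchor, the
directed SL is $|R_x \cap R_y| / |R_x|$ and the reported pair value is the
mean of the two directions. By construction the expected SL of independent
signals is $p_{\mathrm{ref}}$ and the SL of a channel with itself is 1, so
values live on the interpretable scale
$[p_{\mathrm{ref}}, 1]$.

TFSL resolves SL in time and frequency: the epoch is band-pass filtered
into six bands - delta (1-4 Hz), theta (4-8 Hz), alpha (8-12 Hz), beta
(12-30 Hz), gamma1 (30-40 Hz), gamma2 (40-60 Hz) - and SL is evaluated at
20 anchors spaced 25 samples, one per 50 ms window of the first
post-onset second. Embedding parameters per band (lag, dimension):
delta (25, 8), theta (21, 7), alpha (14, 6), beta (6, 8), gamma1 (5, 5),
gamma2 (3, 6); lags shorten with frequency so an embedded vector covers a
comparable phase extent in every band. Per electrode the feature is the
mean SL over the 63 pairs containing it, giving the feature grid
$B_iE_jT_k$: 6 bands x 64 electrodes x 20 windows = 7680 features per
trial.

Key parameter defaults (all exposed in `sl_params()`):

* `p_ref = 0.1` - recurrence probability; anchors the independence
  baseline.
* `candidate_shift = 1` sample - every embedded vector of the epoch is a
  candidate.
* `anchor_shift = 25` samples, `n_anchors = 20` - one anchor per 50 ms
  window at 512 Hz.
* `theiler = (m-1)L` samples - autocorrelation guard; the original
  formulation is silent here, and without it neighbouring vectors count as
  trivial recurrences.

## Numerical and structural choices

* **Anchor-to-window mapping.** 50 ms at 512 Hz is 25.6 samples, so
  windows alternate between 25 and 26 samples
  (boundaries `round(0.05 k f_s)`, half-open) while anchors sit at
  multiples of 25. Strict containment would put two anchors in window 1
  and none in window 20; since the default geometry is plainly *one anchor
  per window*, the k-th anchor maps to the k-th window whenever the counts
  match, and containment (with averaging) applies otherwise.
* **Candidate scope.** Candidate vectors span the full epoch, including
  the embedding tail, rather than a local neighbourhood of each anchor.
  Consequence: a coupling confined to a short time span is diluted in
  proportion to the fraction of candidates it covers, because recurrences
  land mostly outside the coupled region. Detectable synthetic effects
  therefore need either a driver much stronger than the in-band
  background or a span of several hundred milliseconds; the bundled test
  conditions use both (driver 4x the broadband background RMS over
  500 ms).
* **Epoch tail.** Every epoch carries $(m-1)L$ extra samples (175 at the
  defaults, set by the delta band) beyond the analysis second so that
  embedding vectors anchored in late windows are complete; without the
  tail, delta-band vectors cannot be anchored past 650 ms at all.
* **Exact equality of the two SL engines.** The optimized C++ path and
  the plain-R reference path (explicit distance matrices) accumulate
  squared distances in the same order and extended precision and take the
  same order statistic, so they agree bit for bit and the test suite
  asserts `identical()`, not approximate equality.
* **Filtering.** The 10th-order Butterworth band-pass is designed
  analytically in second-order sections (a transfer-function realization
  of this order is numerically singular for the 1-4 Hz band at 512 Hz)
  and applied forward-backward. Zero-phase filtering was chosen because
  the windows are interpreted as post-onset latencies and a causal filter
  would shift them by its group delay; the causal single pass remains
  available (`direction = "forward"`). Odd-reflection padding of the full
  epoch length suppresses startup transients.

# Feature ranking and profiles

The discriminability of each feature is its F-ratio: the variance of the
two class means over the mean within-class variance,

$$FR = \frac{(\mu_1-\bar\mu)^2 + (\mu_2-\bar\mu)^2}
            {(s_1^2 + s_2^2)/2},$$

with unbiased within-class variances (per-class trial counts are small)
and the between-class sum of squares divided by $K-1 = 1$. The phrase
"variance of the means" is ambiguous between the sample and population
conventions; the sample convention is the default and the population
variant (`between = "population"`) halves every score without changing any
rank. Ties are broken by feature id order so rankings are reproducible.

Temporal profiles average the top-k (default 300) F-ratios either over
growing cumulative windows (384 features per step at the default grid) or
per single window; when fewer than k features exist, all are averaged (a
step-one cumulative profile has only 384). Scalp maps average F-ratios
over bands and a window range per electrode; rendering uses
inverse-distance weighting over 2-D positions, with a synthetic
concentric-ring layout when no montage is supplied.

# The decoder

A two-layer feedforward network: 16 tan-sigmoid hidden units, linear
output units, one-hot targets, trained by Levenberg-Marquardt on the mean
squared error (analytic Jacobian; damping starts at $10^{-3}$, x10 on a
rejected step, /10 on an accepted one, abort above $10^{10}$ - the damping
schedule is not prescribed anywhere, this is the conventional one).
Training stops at 100 epochs, at MSE $10^{-5}$, or by early stopping.
Choices that were genuinely open:

* **Output width.** The binary task needs 2 output units and that is the
  default; the historically described 4-unit head is available
  (`n_output = 4`, extra units carry zero targets) but its intent is
  unexplained, so it is reproduced rather than guessed at.
* **Role of the validation set.** A validation partition is named in the
  evaluation protocol without a stated role; here it drives early
  stopping (best-validation weights restored, patience 6), which is
  standard and keeps the test partition out of training entirely.
* **Input standardization.** Features are z-scored with training-set
  statistics. SL features are already bounded, but standardization
  conditions the LM normal equations; it can be disabled.
* **Initialization.** Uniform $\pm 1/\sqrt{\text{fan-in}}$ from a stated
  seed; every evaluation routine derives per-repetition seeds from its
  master seed, so all reported numbers are exactly reproducible.

Evaluation uses stratified 60/20/20 train/validation/test splits repeated
10 times (mean and SD over repetitions), or stratified k-fold
cross-validation for comparison. Sequential forward selection adds
features in descending training-set F-ratio order, retraining after each
addition, and stops when the score has not improved for `patience`
consecutive additions (default 1, the literal "stops when accuracy does
not increase" rule). The score driving selection is validation accuracy by
default; scoring selection on the test partition - as the original
protocol describes - is available via `score_on = "test"` but is
optimistically biased, which is why it is not the default. Ranking inside
SFS uses the training partition only, and SFS is re-run per repetition.

The empirical chance level comes from quasi-randomization: flip the labels
of a random half of the training side of the split (training *and*
validation partitions - flipping only the training labels would let early
stopping re-align the network with the truth), train, and score the
untouched test partition; the mean over 10 runs estimates chance. Flipping
none reproduces the ordinary pipeline; flipping all inverts it.

# The synthetic generator

`generate_trialset()` emulates the recording geometry of the study it is
modelled on: 64 channels at 512 Hz, 1 s epochs plus the embedding tail,
two classes ("chosen" / "not chosen"), multiple participants. Background
activity is independent spectrally shaped Gaussian noise
(power $\propto 1/f$, FFT-shaped, 10 uV RMS). Class information is carried
exclusively by inter-channel synchronization:

* Every *effect electrode* in every trial carries a band-limited driver at
  `coupling_strength` x the background RMS, for the whole epoch.
* In "chosen" trials the drivers of all effect electrodes crossfade to a
  single shared realization inside the *effect windows*:
  $d_e(t) = m(t)\,c(t) + \sqrt{1-m(t)^2}\,o_e(t)$, with $m$ the effect
  window mask ramped by a 10 ms cosine, $c$ shared and $o_e$
  electrode-specific. In "not chosen" trials every electrode keeps its own
  realization.

The crossfade is amplitude-preserving, so band power is identical across
classes, electrodes and time; the two classes differ *only* in
synchronization, confined to the ground-truth (band, electrode, window)
triples. Two earlier designs - switching a shared driver on during effect
windows of chosen trials only, or giving not-chosen trials independent
on/off drivers - both leak class information through the shared amplitude
envelope (recurrence sets concentrate in, or avoid, the high-amplitude
region for both channels at once), and were measured to violate
localization before being replaced. A `matched_power = FALSE` switch
retains the naive on/off behaviour for illustrating that artifact.

For the PAM-vs-CGM contrast the generator supports an idiosyncratic
regime: each participant draws an independent random effect electrode set,
so pooled classifiers dilute the per-participant signal while individual
classifiers retain it. With a shared set the two scopes converge.

What the generator does **not** emulate: volume conduction and a forward
model (channels are independent by construction, real EEG is not), ocular
and muscle artifacts, event-related potentials, non-stationary background
rhythms. Passing tests therefore demonstrate the estimator and decision
chain recover a synchronization effect of known location and strength
under clean conditions; they say nothing about artifact robustness or
about absolute accuracies on real recordings. The study's headline
accuracies depend on effect sizes the paper does not report, and the
generator's coupling strength is a free parameter, so no numeric
comparison to those accuracies is attempted anywhere in the package.

# Study conditions used by the tests and the acceptance script

Chosen once, as the package's desk-scale conditions, and stated here so
the reported numbers are interpretable:

* *Independence baseline*: alpha-band embedding, 100 anchors per
  realization x 20 white-noise realizations; grand mean compared to
  `p_ref` within 3 standard errors.
* *Strong-coupling decoding condition*: 200 trials, 8 channels, alpha-band
  driver at 4x background RMS shared across electrodes {1, 3, 5, 7} during
  windows 3-12 (100-600 ms), features from alpha and beta. This is the
  regime where the localized coupling survives the whole-epoch-candidate
  dilution discussed above.
* *Model-scope condition*: 5 participants x 80 trials, 10 channels, 4
  effect electrodes per participant (random per participant in the
  idiosyncratic regime, common in the shared regime), windows 3-14.
* The embedding-span bleed means windows adjacent to an effect span on
  effect electrodes carry real (not spurious) residual contrast; the
  localization test excludes that one-window halo and the temporal tests
  assert plateaus rather than knife-edge boundaries.

# Known limitations

* Whole-epoch candidates dilute short-lived couplings (discussed above);
  a local-window candidate variant is a possible extension.
* The per-electrode aggregation of pair SL (mean over partners) is one of
  several defensible reductions; it is what makes the electrode-indexed
  feature grid possible but mixes each electrode's pairs.
* SL values at a single anchor are ratios of small counts
  (about 1/48 resolution at the defaults), so single-window features are
  noisy; profiles and classifiers work on many features jointly.
* The LM trainer is dense and in-memory; it is sized for feature counts
  up to a few hundred, which SFS never exceeds in practice.
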