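---
title: "Intermuscular coherence for standing balance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intermuscular coherence for standing balance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(imcoh)
```

## The scientific question

During quiet standing the central nervous system is thought to stabilize the
body by delivering a *common neural drive* to functionally grouped lower-leg
muscles: one presynaptic oscillatory input reaching the motor neuron pools of
several muscles at once synchronizes their firing. If two muscles share such
a drive, their surface EMG signals become correlated at the drive's
frequencies, and the strength of that correlation can be read out with
**magnitude-squared coherence** (MSC),

$$C_{xy}(f) = \frac{|P_{xy}(f)|^2}{P_{xx}(f)\,P_{yy}(f)} \in [0, 1],$$

where $P_{xx}, P_{yy}$ are the auto-spectra of the two EMG channels and
$P_{xy}$ their cross-spectrum. Narrowing the base of support (feet together,
then heel-to-toe tandem stance, with eyes open or closed) is expected to
raise intermuscular coherence in bands associated with corticospinal control
(beta, 13–30 Hz; gamma, 30–100 Hz). `imcoh` implements the complete analysis
chain for such a study — spectral estimation, band averaging, and
per-participant many-to-one inference against a stable baseline condition —
plus a synthetic EMG generator whose true coherence is known in closed form,
so every stage can be validated against ground truth.

## Study layout

The reference design analyzed throughout the package is a factorial layout:
6 participants × 6 standing conditions × 5 trials of 30 s, with 6 muscles
(left/right tibialis anterior TA, medial gastrocnemius MG, soleus S)
sampled at 1200 Hz. Conditions are labeled `EOFT, ECFT, EOTanDB, ECTanDB,
EOTanDF, ECTanDF` (eyes open/closed; feet together or tandem with the
dominant foot back/forward), with `EOFT` as the stable baseline. One
condition label in circulation describes `ECTanDB` as "dominant foot
forward"; the package follows the abbreviation semantics (DB = dominant
foot back). Nine muscle pairs are defined (three left-unilateral, three
right-unilateral, three bilateral-homologous); by default the bilateral
plantarflexor pairs `LMG:RMG` and `LS:RS` are excluded as showing
insufficient EMG connectivity, leaving 7 pairs. Four bands are analyzed by
default (alpha, beta, lower gamma, upper gamma); delta and theta are defined
but excluded because the 10 Hz acquisition high-pass removes most of their
signal. This yields 6 × 7 × 4 = **168 analysis sets of 30 coherence
values** (6 conditions × 5 trials) and 5 baseline comparisons per set.

## Spectral estimation

MSC is estimated with Welch's overlapped-periodogram method: 2 s symmetric
Hamming windows with 25% overlap. "25% overlap" is a fraction of the window
length: the hop is $W - \mathrm{round}(0.25\,W)$ samples. On a 30 s trial at
1200 Hz this gives 19 segments of 2400 samples and a 0.5 Hz frequency grid —
the alternative reading (hop = 25% of the window) would give 57 segments and
is ruled out by that bookkeeping, which is asserted as a regression test.
Spectra are one-sided; the density scaling cancels in the MSC ratio, which
is confirmed by test. Segments are not detrended by default (a constant
detrend option exists): the acquisition high-pass has already removed DC
and the lowest analyzed band starts at 8 Hz. With $L$ segments the null
(zero-coherence) estimate concentrates around $1/L$, and the $(1-\alpha)$
null quantile is $1 - \alpha^{1/(L-1)}$ (`zero_coherence_bound()`, ≈0.153
for $L = 19$); the estimator's expectation at true coherence $\gamma^2$ is
approximately $\gamma^2 + (1-\gamma^2)^2/L$, which the calibration tests use
as the bias-corrected target.

Band averaging uses half-open intervals $[lo, hi)$ — delta 0–4, theta 4–8,
alpha 8–13, beta 13–30, lower gamma 30–60, upper gamma 60–100 Hz — so that
shared printed endpoints (13 Hz, 30 Hz, 60 Hz) assign each 0.5 Hz bin to
exactly one band and the six bands tile $[0, 100)$ without overlap. The
band value is the unweighted mean of MSC bins in the interval; bins where an
auto-spectrum vanishes are reported as undefined (`NA`), excluded from the
mean, and counted, never coerced to 0 or 1. MSC is computed per 30 s trial,
not pooled across trials, because each analysis set needs independent
per-trial replicates for inference. No rectification is applied before
coherence by default; a rectify-first flag exists for comparison with
related work.

## Preprocessing

Powerline interference is removed with a 60 Hz 2nd-order Butterworth
band-stop filter whose 0.2 Hz bandwidth is interpreted as the −3 dB width of
the stop band (the standard notch-design convention; verified on the
realized transfer function). Filtering is single-pass (causal) by default.
The 10 Hz 2nd-order Butterworth high-pass emulating the acquisition chain is
applied only in the simulation path; real recordings are assumed already
hardware-filtered. The high-pass order is a package choice — acquisition
specifications rarely state it.

Two numerical facts about filtering deserve emphasis, because they shape the
test tolerances:

* **Invariance is exact for the estimand, approximate for the estimator.**
  True MSC is invariant to any per-channel LTI filtering applied to both
  channels. The Welch *estimator* is not exactly invariant: filtering does
  not commute with windowed segmentation, so causal IIR filtering perturbs
  individual bins at the few-percent level (segment-boundary phase effects),
  and even exact zero-phase filtering perturbs them at the ~10⁻³ level
  through window leakage of the modified near-notch content. Per-channel
  *scaling* is exactly invariant. The invariance suite therefore asserts
  machine-precision scale invariance, ≤5×10⁻³ per-bin deviation for
  zero-phase filtering, and ≤5×10⁻² for causal filtering (band averages are
  an order of magnitude more stable). Because both channels of a pair pass
  through identical filters, none of this biases condition contrasts.
* **The narrow notch rings.** A 0.2 Hz-wide resonator decays with time
  constant ≈ $1/(\pi \cdot 0.1\,\mathrm{Hz})$ ≈ 3.2 s. Tests of tone
  suppression discard several ring-down constants before measuring causal
  attenuation; the zero-phase path (which applies the two-pass magnitude
  response $|H|^2$ in the frequency domain and has no ring-in) reaches full
  suppression immediately. `signal::filtfilt` was not used for the
  zero-phase path because its uninitialized edges leave ~10⁻³ artifacts.

## The synthetic generator

Because MSC validation needs known ground truth, trials are generated from a
deliberately simple linear mixing model, not a biophysical EMG synthesis:
each muscle receives independent broadband (10–500 Hz, flat) Gaussian noise,
and a keyed (condition, pair, band) cell adds one shared band-limited
Gaussian drive realization to both muscles of the pair. For drive-to-noise
power ratio $r$ in band, the true coherence is

$$\gamma^2 = \left(\frac{r}{1+r}\right)^2,$$

the unit-gain case of
$\gamma^2 = (a_1 a_2 S_s)^2 / ((a_1^2 S_s + S_{n1})(a_2^2 S_s + S_{n2}))$.
`snr_for_coherence()` inverts this, so an effect map can plant an exact
target coherence; $r = 1$ gives $\gamma^2 = 0.25$, the planted value used in
the end-to-end suites. Band-limited signals are produced by spectral masking
of white Gaussian noise, giving exactly flat in-band density. Amplitudes are
nominally microvolt-scale but arbitrary, since MSC is scale-invariant.

Reproducibility follows a counter-based seed discipline: a single top-level
seed deterministically spawns one sub-seed per (participant, condition,
trial, channel) and per planted drive, so regeneration is bit-identical and
trials are mutually independent. Optional 60 Hz interference (random
per-trial phase) exercises the notch, and the emulated acquisition
high-pass is on by default.

What the generator does *not* emulate — motor-unit action potential shapes,
recruitment and firing-rate modulation, amplitude non-stationarity, EMG
cross-talk, electrode artifacts — bounds what passing tests show: they
validate the estimation and inference chain, not robustness to physiological
signal structure. The planted effect sizes are free parameters of the
simulation, chosen for clear detectability ($\gamma^2 = 0.25$ against a null
floor of ≈0.05), not reproductions of any measured effect.

## Inference

Within each analysis set the question is many-to-one: does mean coherence
under each less-stable condition differ from the baseline? This is Dunnett's
problem. With group sizes $n_i$ and pooled within-group variance $s_p^2$ on
$df = N - g$ degrees of freedom, the statistics
$T_i = (\bar y_i - \bar y_0) / (s_p\sqrt{1/n_i + 1/n_0})$ follow a
$k$-variate t distribution with product correlation
$\rho_{ij} = \lambda_i \lambda_j$, $\lambda_i = \sqrt{n_i/(n_i+n_0)}$
(balanced: $\rho = 1/2$ exactly). The package computes
$P(\max_i |T_i| \le d)$ by the classic one-factor reduction — conditioning
on the shared normal factor and the pooled-variance scale makes the
comparisons independent — evaluated with fixed 96-point Gauss–Legendre
quadrature in both dimensions. This is deterministic to ~10⁻⁸ (checked
against an independent quasi-Monte-Carlo multivariate-t integrator and a
10⁶-draw simulation), and fast enough to be applied per analysis set.
Two-sided comparisons are used, since both increases and decreases in
coherence are of interest, with $\alpha = 0.05$. The simultaneous intervals
$\bar y_i - \bar y_0 \pm d\, s_p \sqrt{1/n_i + 1/n_0}$, adjusted p-values
$1 - P(\max|T| \le |t_i|)$, and significance flags are mutually consistent
by construction; a degenerate (zero-variance) family is flagged rather than
reported as significant.

Coherence values are analyzed untransformed. They live in $[0,1]$ and are
mildly non-normal, but deviations are small at these effect sizes and the
parametric approach keeps the intervals interpretable on the coherence
scale; a Fisher-z option exists but is off by default. Shapiro–Wilk
normality screens per condition, Levene's homogeneity test
(mean-centered classic form by default, median-centered optional) and the
one-way ANOVA F-test are reported on request and never auto-remediate: the
omnibus F answers a different question (any difference among all
$\binom{6}{2} = 15$ pairs) than the 5 baseline contrasts of interest, which
is precisely why the many-to-one procedure is preferred. Trials are treated
as independent replicates; no pooling across participants is performed
(each participant is their own analysis), and no correction is applied
across the 168 sets.

## Problem sizes and numerical choices

The default test and validation runs use the full reference layout (1080
recordings of 36 000 samples; a complete simulate-plus-analyze cycle takes
well under a minute on a single core). Estimator-calibration suites use 50
independent 30 s pairs; convergence checks use records up to 320 s at a
reduced sampling rate, where only segment count matters. Critical values
are cached per (k, df, alpha, group-size) signature. Root-finding for the
critical value is bracketed between the unadjusted and Bonferroni t
quantiles, which always contain it. Monte-Carlo acceptance bands (familywise
error in [0.03, 0.07] over 2000 null replicates, ≥85% of null band values
below the zero-coherence bound) were fixed from binomial considerations at
the stated replicate counts before the suites were run.

## Known limitations

* The generator's stationary Gaussian model understates the variability of
  real EMG coherence; inter-participant and inter-trial spread in real data
  is biological, not just estimation noise.
* Undefined-bin handling matters only for pathological inputs (a silent
  channel); real EMG never has exactly zero power in a 0.5 Hz bin.
* The one-factor quadrature requires the many-to-one product correlation
  structure; arbitrary correlation matrices are rejected rather than
  approximated.
* EDF/biosignal ingestion is out of scope; the canonical interchange format
  is the long-form CSV with JSON sidecar.
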