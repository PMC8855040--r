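---
title: "Methods: complexity and connectivity analysis of aging EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complexity and connectivity analysis of aging EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`eegcomplexity` implements an analysis chain for 16-channel resting-state
EEG that contrasts a younger and an older group on three signal properties
and then fuses them into an aging classifier:

1. **Wavelet-leader multifractal analysis** — per channel, the log-cumulants
   `c1` (overall regularity; the peak location of the singularity spectrum
   `D(h)`) and `c2 <= 0` (multifractal width; `|c2|` indexes intermittency).
2. **Multiscale sample entropy** — sample entropy of coarse-grained copies
   of the signal at scales 1–30; the mean over the fast scales 1–5
   (0.005–0.025 s at 200 Hz) is the classification feature.
3. **Phase-lag-index (PLI) connectivity** — band-wise pairwise PLI averaged
   over ten 5-s epochs, summarized per electrode as node strength (NS).
4. **Group statistics and classification** — mixed-design repeated-measures
   ANOVA with Greenhouse–Geisser correction and partial eta squared,
   BH-FDR-corrected post-hoc Welch t-tests, Spearman NS–complexity
   correlations, and logistic regression on principal components fitted
   *inside* cross-validation, scored by repeated-CV ROC/AUC.

Because clinical recordings of this kind are not publicly deposited, the
package ships a synthetic cohort generator whose defaults emulate the study
conditions (32 younger vs 18 older subjects, 16 channels of the 10–20
montage, 200 Hz, 60 s per subject) and whose group contrasts follow the
reported *directions* of the aging effects. All tests and the acceptance
script run on these synthetic cohorts.

# Signal conditioning

A recording is bandpass filtered to 2–60 Hz with a 4th-order Butterworth
filter applied forward–backward (`signal::filtfilt`), i.e. zero-phase. The
zero-phase choice matters: PLI compares Hilbert phases across channels, and
a causal filter would add frequency-dependent phase shifts. The first 60 s
(12,000 samples) form the analysis epoch; 5 s (1,000 samples) are trimmed
at each end to discard filter transients, leaving the 10,000-sample
"complexity" epoch. For PLI this epoch is cut into ten contiguous 5-s
epochs of 1,000 samples: short epochs inflate PLI, long epochs lose slow
bands, and ten 5-s epochs with averaging is the balance used here. Band
decomposition uses the canonical delta (2–4), theta (4–8), alpha (8–13),
beta (13–30) and gamma (30–60 Hz) bands, each a zero-phase Butterworth pass
of the already broadband-filtered epoch. Indexing is 0-based half-open in
the documentation of epoch arithmetic; seconds convert to samples via the
sampling rate.

Relative band power (the ANCOVA covariate uses the gamma band averaged over
electrodes) is computed from a Welch PSD — 2-s Hann windows, 50% overlap —
integrated with the trapezoid rule and normalized by total 2–60 Hz power.

# Wavelet-leader multifractal analysis

The detail coefficients come from a Mallat pyramid with a Daubechies
wavelet (db3 by default; at least 2 vanishing moments are required so that
polynomial trends vanish). Coefficients are L1-normalized (`2^(-j/2)` times
the orthonormal-pyramid value) so that fractional Brownian motion with
Hurst exponent `H` has linear scaling exponents `zeta(q) = qH`. The causal
pyramid marks boundary-contaminated positions as `NA`; they are excluded
from all fits and the surviving counts `n_j` weight the regressions.

The leader at scale `j`, position `k` is the supremum of absolute
coefficients over all dyadic intervals at scales `<= j` inside the
3-neighborhood of the interval at `(j, k)` — computed by the standard
bottom-up recursion and verified in the tests against an exhaustive
brute-force supremum. Structure functions `S_L(q, j)` are moments of the
leaders; `zeta_L(q)` is the weighted-least-squares slope of
`log2 S_L(q, j)` on `j`. The singularity spectrum is the discrete Legendre
transform `D(h) = min over q != 0 of (1 + qh - zeta_L(q))` on the moment
grid `q in [-5, 5]` step 0.25 without 0. The log-cumulants are estimated
from the sample cumulants of `log L(j, .)`: `c_p` is `log2(e)` times the
slope of the p-th cumulant against `j` — the standard, lower-variance
estimator compared with differentiating `zeta`.

Numerical choices:

* **Fractional integration (`gamint = 0.5`).** Leader suprema converge
  slowly at low regularity; at `N = 2^14`–`2^15` the raw estimator is
  biased low by up to ~0.06 for `H = 0.3`. Scaling the coefficients by
  `2^(j * gamint)` (analysing a fractionally integrated copy) and
  subtracting `gamint` from `c1` — a standard pseudo-regularization —
  brings the mean bias within ±0.04 across `H in [0.3, 0.8]` and leaves
  `c2` untouched.
* **Fit range.** For unfiltered series the default is `j = 3` to
  `floor(log2 N) - 3`, shortened if a coarse scale retains fewer than 8
  leaders. For the pipeline's 2–60 Hz filtered epochs the fit uses
  `j = 3..6` — the dyadic scales overlapping the passband (about 1.6–25 Hz
  at 200 Hz); coarser scales of a high-passed signal measure filter
  rolloff, not signal scaling.
* `q = 0` is excluded (the spectrum is defined through an infimum over
  `q != 0`); non-finite `zeta` values are dropped from the infimum with a
  count.

# Multiscale sample entropy

Sample entropy uses embedding `m = 2`, tolerance `r = 0.2`, Chebyshev
distance, self-matches excluded, each unordered template pair counted once;
the entropy is `-ln(A/B)` of the (m+1)- to m-length match counts. Each
channel is z-scored once and `r` stays fixed at 0.2 (in units of the
scale-1 SD) for all coarse-graining scales, so the scale profile reflects
loss of fast variance rather than a moving tolerance. Coarse-graining is
the non-overlapping block mean, dropping a trailing partial block. A zero
match count yields a flagged missing value, never ±infinity. The C++
kernel prunes candidate pairs by sorting on the first coordinate and is
exactly equal (same counts) to the naive O(N^2) double loop, which the
tests verify.

# Phase-lag index

Hilbert phases come from the FFT analytic signal; 5% of samples at each
epoch edge are excluded from PLI sums (analytic-signal transient — the
transform is circular and the epoch is not). The PLI of two channels is
`|mean(sign(dphi))|` with the phase difference wrapped to `(-pi, pi]`.
Read literally, a "mod 2 pi" difference would be non-negative and the PLI
identically 1; wrapping into `(-pi, pi]` — so that `sign(dphi_mod) =
sign(sin(dphi))` — is the standard definition and the central
interpretation decision of this module. `sign(0) = 0`, so zero-lag
coupling contributes nothing; phase differences below 1e-8 rad are treated
as zero so that amplitude-scaled copies of one source give PLI exactly 0
despite floating-point residue. Per-band matrices are computed per 5-s
epoch and averaged over the ten epochs; node strength is the row mean over
the other `K - 1 = 15` electrodes.

A statistical floor worth knowing: for channels with *independent* phases,
the expected PLI of a T-sample epoch is about `sqrt(2 tau / (pi T dt))`
where `tau` is the phase decorrelation time (at best the inverse band
width). In delta at 5-s epochs this floor is ~0.2 for any data — which is
why spurious-connectivity checks here use a *pure* common source (PLI
exactly 0 by the zero-lag property) and, for partial mixing, bound the
maximum over the 120 pairs by 0.2 in beta/gamma rather than by the floor
itself.

# Group statistics

The mixed (split-plot) ANOVA has group (younger/older) between subjects
and electrode — and, for entropy, temporal scale — within subjects. Sums
of squares come from the standard `aov` error strata (the within design is
balanced; unequal group sizes are fine and leave the effects orthogonal).
Greenhouse–Geisser epsilon is computed per within effect from the pooled
within-group covariance of the contrast-transformed responses
(orthonormal contrasts; Kronecker products for interactions), bounded to
`[1/df, 1]`, and applied to both degrees of freedom; epsilon is exactly 1
under compound symmetry, recovering the uncorrected test. Partial eta
squared is `SS_effect / (SS_effect + SS_error)` within each effect's
stratum. The ANCOVA variant enters the subject-level covariate (gamma
relative power averaged over electrodes) first in the between-subjects
stratum, so the group effect is covariate-adjusted (sequential sums of
squares).

Post-hoc comparisons are Welch two-sample t-tests — chosen because the
group sizes differ (32 vs 18) and equal variances are not assumed — with a
single Benjamini–Hochberg step-up mask per comparison family at `q < 0.05`
(families: 16 electrodes; 480 electrode-scale cells; 600 pair-band cells;
80 electrode-band cells). BH is defined on p-values; the t-map is reported
alongside, with t > 0 meaning higher in the older group. Spearman
correlations (average ranks for ties) relate per-channel node strength to
`c1` or `|c2|` within one group, masked by BH over the 16 channels.

# Classification

For a named feature set (blocks among `c1`, `|c2|`, fast-scale entropy,
and NS per band), the subject-by-feature matrix is column-standardized and
labels are older = 1. Each of 20 repeats draws a fresh stratified 5-fold
split; within each fold PCA is fitted on the training folds only and the
first 3 components feed a ridge-regularized logistic regression (fixed
`lambda = 1/n`, for numerical stability at n = 50; the penalty is small
enough not to affect separable endpoints). Held-out probabilities are
pooled across the 5 folds into one ROC per repeat; the AUC is the
Mann–Whitney rank statistic, identical to the trapezoidal ROC area (the
tests cross-check against an independent ROC implementation). Feature sets
are compared by a paired t-test across the 20 per-repeat AUCs, pairing by
repeat (splits are seeded from `(seed, repeat)` and therefore shared).
Decision regions evaluate the full-data model over a grid on two principal
components with the remaining components at their grand means and mark
where the predicted probability of "older" exceeds 0.9.

When PCA is applied to a *combined* feature set it is fitted on the
concatenated blocks (a per-block option exists at assembly level by
calling the classifier per block); which of the two the original analysis
used is not determinable from its description.

# The synthetic cohort generator

Each channel is built as

```
channel = backbone(H_group, lambda2_group)
        + noise_gain_group * highpass_30Hz(white noise)
        + 0.15 * alpha oscillation (drifting phase)
        + coupling components (shared narrowband oscillation, fixed lag)
mixed with a zero-lag broadband common source (mixing fraction 0.05)
```

* **Backbone.** A multifractal random walk: fGn increments modulated by
  `exp(omega)` with `omega` a log-correlated Gaussian field (covariance
  `lambda2 * ln(L/(k+1))`, integral scale `L = n`; `c2` estimates depend
  only weakly on this choice). Both the fGn and `omega` are sampled
  *exactly* by circulant embedding. The construction's linear exponent is
  `H + lambda2`, so the fGn uses exponent `H - lambda2` and the requested
  `hurst` is the target `c1`; `c2 = -lambda2`. With `lambda2 = 0` this is
  exact fractional Brownian motion (Davies–Harte).
* **In-band standardization.** The walk's sub-2-Hz variance dominates its
  total power but is removed by the pipeline's 2–60 Hz filter, so the
  backbone is band-limited to 2–60 Hz and standardized to unit power over
  the dyadic-scale window `fs/32..fs/8` (the scales where the cumulants
  are fitted). This makes both groups present equal amplitude at the
  fitted scales; otherwise any equal-amplitude admixture erodes the
  steeper younger spectrum faster and can invert the c1 contrast.
* **Fast noise.** Group-scaled white noise high-passed above 30 Hz: it
  raises sample entropy at scales 1–5 (periods 5–25 ms) without touching
  the c1/c2 fit scales (~1.6–25 Hz). The older group's gain is 1.5 times
  the younger group's.
* **Oscillations.** All oscillatory components carry a random-walk phase
  (0.3 rad/sample SD): pure sinusoids would make PLI saturate at 1
  regardless of coupling strength and would never decorrelate within an
  epoch. Coupled edges share one phase track with a constant lag; the
  second channel receives it lagged, and amplitude `2 * strength` makes
  the coupled component dominate the band so PLI tracks the edge.
* **Common source.** The zero-lag broadband source is mixed at fraction
  0.05: a white source mixed at fraction g contributes about `7 g^2 / 1.3`
  of the backbone's power spectral density at the top fitted scale, so
  g = 0.05 keeps that contamination near 1% and leaves the group scaling
  contrast intact while still exercising the PLI volume-conduction
  property.
* **Defaults.** Younger `H = 0.80`, `lambda2 = 0.08`, noise gain 0.2;
  older `H = 0.70`, `lambda2 = 0.03`, noise gain 0.3. The study reports
  only directions (older: lower c1, lower |c2|, higher fast-scale
  entropy), not effect sizes, so the defaults are calibrated to sign, not
  magnitude. Alpha couplings C3–C4 (strength 0.8) and O1–O2 (0.6) and a
  theta coupling F3–F4 (0.5) are identical across groups.

What the generator does **not** emulate: volume-conduction head geometry,
electrode forward models, artifacts (blinks, EMG), non-stationary arousal
drift, or realistic cross-frequency structure. Passing tests therefore
demonstrate that the *pipeline* recovers planted signal properties and
directions, not that real aging EEG will show effects of any particular
size.

# Problem sizes and determinism

Simulation-based tests use sizes chosen to give stable Monte-Carlo means:
parameter recovery runs 50 replicates at `n = 2^15` (tolerances ±0.05 on
c1, ±0.02 on c2); the directional check runs one default 50-subject
cohort; the AUC-ordering property (combined complexity + NS-alpha at least
as good as NS-alpha alone) uses 10 independent cohort draws with 5 CV
repeats each. Every stochastic step is seeded; cohorts are bit-for-bit
reproducible given the seed, and seeded generators restore the caller's
RNG state.

# Known limitations

* The wavelet-leader c1 retains a residual bias of a few hundredths at
  these signal lengths; tolerances reflect that.
* `c2` estimated on band-limited signals is attenuated (the filter removes
  part of the cascade's scale range), so cohort-level `|c2|` contrasts are
  direction-true but smaller than `lambda2` differences.
* The repeated-measures machinery supports at most two within factors
  (electrode and scale), which covers all designs used here.
* EDF support covers continuous recordings with a common sampling rate —
  enough to round-trip generated cohorts and read plain continuous EDF.
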