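---
title: "Operational ROC analysis: methods, calibration, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operational ROC analysis: methods, calibration, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rocboot)
```

## The data model

The package analyses two samples of match scores: a genuine set **G**
(N_G same-subject comparisons) and an impostor set **I** (N_I
different-subject comparisons). Scores are treated as i.i.d. draws within
each class. Everything is empirical: no parametric family is fitted to
either distribution, because operational score distributions are discrete,
heavily tied, often multimodal, and can carry point masses (e.g. a
stand-alone spike of genuine scores at the maximum score). The two
distributions are interrelated — both are produced by the same matcher —
so all statistics are functionals of the *pair*.

The discrete support {s} runs from the lowest to the highest observed
score. When the scores sit on a regular decimal grid (integers, or
multiples of 10^-d for d ≤ 6, detected automatically; the `"decimal"`
discretization mode forces rounding onto such a grid), the support is the
complete grid *including unused values*. This matters: operating points
between occupied scores belong to the score scale, and the equal-error
scan must see them — with a separating gap between the classes there are
unused thresholds at which both error rates vanish, and the EER estimate
must be exactly zero there. Only irregular real-valued scores fall back to
the union of distinct observed values; for such data we recommend the
decimal mode (choose `digits` at the resolution the scores are reported
with), which reproduces the integer-conversion convention the methodology
was developed under. The grid is capped at 10^6 points, beyond which
distinct observed values are used.

On the support, `score_distribution()` stores per-class probabilities
P_i(s) and *top-down* cumulatives C_i(s) = Σ_{τ≥s} P_i(τ), so that
TAR(s) = C_G(s) and FAR(s) = C_I(s) directly.

## The three operating-point statistics

**TAR at a specified FAR** (`tar_at_far()`). The threshold t is the
support value with C_I(next(t)) < f ≤ C_I(t), where next(s) is the next
larger support value and cumulatives beyond the maximum are zero; the
impostor mass P_I(t) is then necessarily positive. Genuine ties at t are
divided proportionally — linear interpolation along the inclined ROC
segment:

TAR(f) = C_G(next(t)) + P_G(t) · (f − C_I(next(t))) / P_I(t).

With large, tied score sets this tie division is not a refinement but the
difference between a usable estimate and a step artifact.

**Rates at a threshold** (`rates_at_threshold()`). An arbitrary real
threshold is mapped to its support ceiling s (smallest support value ≥ t);
the rates are C_G(s) and C_I(s). Thresholds above the maximum score accept
nothing; at or below the minimum, everything.

**EER** (`eer()`). At each support value, ER_I(s) = 1 − C_G(next(s)) and
ER_II(s) = C_I(s) (with C_G beyond the maximum taken as 0). This
asymmetric offset is kept exactly as the methodology defines it — ER_I
uses next(s), ER_II uses s — because the pair brackets the crossing of two
step functions; "correcting" ER_I to 1 − C_G(s) would change the
statistic. ER_I is non-decreasing and ER_II non-increasing in s, so
|ER_I − ER_II| attains its minimum on a contiguous range [s₁, s₂] (the
scan asserts contiguity). The EER is the midpoint of the two rates there;
the reported threshold is the largest support value not exceeding
(s₁+s₂)/2, the floor generalized to non-integer supports. Degenerate
detail: if the minimizing range straddles a sign change of the difference,
the midpoint can vary across the range; we report the mean of the
midpoints (on ordinary data the rates, hence the midpoint, are constant
across the range).

Because the distributions are discrete, the minimum gap is rarely exactly
zero; half the residual gap relative to the EER is reported as the
*systematic error* (zero when the EER is zero). One published
worked example prints this ratio as 0.51 % where the printed operands give
0.503 %; the package reports the unrounded value.

**AURC** (`aurc()`) is the Mann-Whitney statistic (ties one half),
computed by midranks in O((N_G+N_I) log(N_G+N_I)); it equals the
trapezoidal area under the ROC polyline to machine precision, which the
tests assert. **Weighted cost** (`weighted_cost()`) is
w₁·(1 − TAR(t)) + w₂·FAR(t). The **FNMR transform** (`fnmr_transform()`)
maps TAR summaries to FNMR = 1 − TAR: SEs are invariant, CI bounds swap.

## Bootstrap uncertainties

`roc_bootstrap()` implements the nonparametric two-sample bootstrap: per
replication, N_G genuine and N_I impostor scores are drawn independently
with replacement and the statistic is re-evaluated; B replications give
the SE (sample SD, divisor B − 1 — the methodology does not state the
divisor; the standard estimator is used and documented here) and two 95 %
CI styles: the percentile interval using the quantile definition that
inverts the EDF with averaging at discontinuities (`quantile_def2()`,
Hyndman–Fan definition 2, with x₍ₙ₊₁₎ := x₍ₙ₎ guarding the extreme
integer-np boundary), and the normal-approximation interval centred on the
original-sample estimate. Agreement of the two to the third or fourth
decimal is the working evidence that the statistic's bootstrap
distribution is normal enough for Z-tests; the package computes both so
the user can check rather than assume.

Implementation note: resampling N scores with replacement and re-counting
them on the support is exactly a multinomial draw over the support counts,
so replications are generated as `rmultinom()` columns and evaluated
vectorially in O(K) per replication (K = support size) instead of O(N).
This is an identical distribution, not an approximation. Draw order is
documented (genuine block, then impostor block) and the replication
sequence is a pure function of `(seed, B)`. Degenerate samples (a constant
class) yield identical replications, SE exactly 0, and both CIs collapsed
to the point estimate.

`bootstrap_variability()` (Algorithm-II-style study) reruns the bootstrap
L times per candidate B and reports coefficients of variation (variance
divisor L − 1, again documented rather than prescribed) of the SE and of
the two percentile bounds. CV_SE decreases with B; B is chosen as the
smallest value bringing CV_SE under a tolerance, customarily 2 %, which
B = 2000 meets with margin — hence the package default `B = 2000`. For
TAR-type statistics whose bounds sit near 1, CV_LB and CV_UB are orders of
magnitude smaller than CV_SE (the bounds' means are near 1 while the SE's
mean is small); on the FNMR scale (`transform = "fnmr"`) the bound CVs
grow but stay within tolerance, so the same B holds. The study derives one
substream seed per (B, run) cell from the master seed, making every cell
independently reproducible and the loops embarrassingly parallel. L
defaults to 100; the choice is numerical (stability of the CV estimates),
not statistical, and L is exposed as a parameter.

## Significance tests

Under the normality working assumption, `one_algorithm_test()` computes
Z = (T̂ − μ₀)/SE(T̂) and `two_algorithm_test()`

Z = (T̂₁ − T̂₂) / √(SE₁² + SE₂² − 2 r SE₁ SE₂),

both with two-tailed p-values 2(1 − Φ(|Z|)); one-tailed testing is
deliberately not offered (two-tailed is the conservative choice, and the
sign of the difference plus the metric's orientation decides who wins).
The orientation (larger-is-better for TAR/AURC, smaller-is-better for
EER/FNMR/cost) is always supplied by the caller, never inferred from the
data. With r = 0 the two-algorithm test reduces to the unpaired Z;
ignoring a positive r only shrinks |Z|, so the correlation adjustment can
only help detect real differences. If r ≈ 1 with equal SEs the radicand
vanishes: equal estimates return Z = 0, p = 1, otherwise the degeneracy is
an error.

`synchronized_correlation()` estimates r: per iteration one
with-replacement index vector per class is drawn and applied to *both*
algorithms' ordinally paired score lists (a selected score of A drags
along the co-varying score of B — same ordinal position, same underlying
comparison), the statistic is evaluated per algorithm, and the Pearson
correlation (the unqualified "correlation coefficient" is read as
product-moment) across the M = 2000 iterations is computed; the average of
`runs = 10` independent runs is reported to damp Monte Carlo fluctuation.
Index-level sampling is essential here — the multinomial shortcut would
discard the pairing. Shuffling one algorithm's score order destroys the
pairing and drives r to zero, which the tests verify.

## The synthetic generator

`simulate_scores()` draws the two classes from Gaussian distributions
(location/scale per class), rounds to `decimals` digits (default 2, a
typical reporting resolution, which also puts the sample on a decimal grid
and exercises ties), and optionally replaces genuine scores, with
probability `spike_mass`, by the value location + 5·scale — effectively
the maximum of the genuine support, emulating the stand-alone top-score
peak of real matchers. Gaussian margins are a convenience, not a claim:
the methods under test are distribution-free, and any unimodal family
would serve. Defaults are N_G = 500, N_I = 1000, preserving the 1:2
genuine:impostor ratio of the motivating application at test-friendly
size. Two presets fix the separation: `preset_high_accuracy()` (genuine
five impostor-SDs above the impostor mean; population EER ≈ 0.006, the
regime of a strong matcher) and `preset_low_accuracy()` (three SDs;
EER ≈ 0.07). `simulate_paired_algorithms()` couples two algorithms through
a shared latent standard normal per comparison (Gaussian copula with
correlation `latent_rho`; spike indicators shared within a pair), so
latent_rho = 1 with identical parameters reproduces identical samples and
latent_rho = 0 independent ones.

What the generator does *not* emulate: dependencies among comparisons
(multiple acquisitions per subject — the bootstrap here assumes i.i.d.
scores; clustered resampling is out of scope), skewed or multimodal score
shapes, and any particular matcher's numerical score range. Passing tests
therefore demonstrate correctness of the estimators and calibration logic
under the structural features they must handle (discreteness, ties, point
masses, correlation), not performance claims about any real system.

## Problem sizes used in the checks

The published calibration used samples of ~60 000 genuine and ~120 000
impostor scores, L = 500 Monte Carlo repetitions, and FAR = 0.001 (about
120 impostor tail instances). The package's own study-scale checks keep
the operational logic at a size chosen for routine re-running: samples of
5 000/10 000 with FAR = 0.01 (100 tail instances, the same tail-count
logic), L = 100, B from 200 to 2000; bootstrap-vs-analytic AURC SE
agreement at N_G = N_I = 500 with B = 2000; synchronized correlation at
M = 2000 over 10 runs. At these sizes the CV of the bootstrap SE at
B = 2000 falls below the 2 % tolerance, percentile and normal CIs agree to
about three decimals on the high-accuracy preset, and the bootstrap AURC
SE lands within a few percent of the closed-form Mann-Whitney SE.

## Known limitations

* i.i.d. scores only; no dependency-grouped (clustered) bootstrap.
* Percentile (definition-2) and normal intervals only; no BCa or
  studentized bootstrap.
* No smooth/parametric (binormal) ROC fitting, no partial AUC, and no
  1-to-n identification (CMC) analysis.
* For irregular real-valued scores in `"distinct"` mode the support
  carries no between-score operating points; a separating gap then yields
  a positive EER bracketing artifact. Use `"decimal"` mode at the data's
  reporting resolution.
* The normality of bootstrap replications is a working assumption checked
  indirectly (CI agreement), not enforced; external normality tests can be
  applied to the exported replications.

```{r curve, fig.width = 4, fig.height = 4}
s <- simulate_scores(preset_low_accuracy(n_genuine = 300, n_impostor = 600),
                     seed = 7)
autoplot(roc_curve(s))
```
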