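---
title: "Comparing phase-angle distributions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing phase-angle distributions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ustpl)
```

## The problem

Inter-areal phase locking is a standard way to look for functional
coupling in MEG/EEG: extract, trial by trial, the phase difference
between two regions at one time and frequency, and ask whether those
differences are consistent across trials. The classical route tests the
phase differences against circular *uniformity* (Rayleigh test on the
phase locking value). That null is wrong whenever the two source
estimates share signal for instrumental reasons — source leakage
("crosstalk") from the ill-posed inverse problem concentrates phase
differences near 0 or π even when the underlying sources are unrelated,
and the uniformity test then fires on nothing.

The remedy implemented here is to stop assuming the null and *sample*
it: take the phase-difference distribution from an empirical baseline —
a prestimulus window, resting state, or a control condition — and test
whether the period of interest differs from that baseline. The test
must be non-parametric (the baseline distribution is arbitrary), cheap
(it runs once per time–frequency point per region pair, often thousands
of times per analysis), and sensitive to any distributional change, not
just a change in resultant length.

## The uniform scores test

Given two populations of phase angles with sizes $n_1$ and $n_2$
($n = n_1 + n_2$), all angles are pooled and ranked from 0 in the
positive direction; rank $r$ is replaced by the *uniform score*
$\beta = 2\pi r / n$. The scores are exactly evenly spaced on the
circle, so under exchangeability the only thing that distinguishes the
populations is *which* ranks each occupies. The test statistic is the
squared resultant of one population's scores,

$$R_k^2 = \Big(\sum_{i=1}^{n_k} \cos\beta_i^{(k)}\Big)^2 +
          \Big(\sum_{i=1}^{n_k} \sin\beta_i^{(k)}\Big)^2,$$

normalized as

$$R^*_k = \frac{2\,(n-1)\,R_k^2}{n_1 n_2},$$

whose null distribution approaches $\chi^2$ with 2 degrees of freedom
for $n > 40$ (the classical two-sample uniform-scores result; because
all $n$ scores sum to the zero vector, the two group resultants are
equal and opposite and the statistic does not depend on which
population is scored). `ustpl_test()` uses the asymptotic tail for
$n > 40$ and otherwise falls back to the permutation distribution,
upgrading to full enumeration whenever $\binom{n}{n_1} \le 10^5$.

Design notes on this statistic:

* **Reading of the normalization.** The normalization is applied to the
  *squared* resultant; that is the only reading under which the
  $\chi^2(2)$ limit holds, which we verified directly (10⁴ null
  replicates at $n_1 = n_2 = 25$ give mean $R^*$ within Monte-Carlo
  error of 2 and a Kolmogorov–Smirnov distance below 0.02 from
  $\chi^2_2$ — the acceptance tests recompute both). An unsquared
  variant circulates in some presentations; it is available as
  `ust_statistic(..., normalization = "root")` for comparison but is
  never used for inference.
* **Ties.** Quantized phases can tie. Average ranks would break the
  exact equal spacing of scores that the null distribution assumes, so
  ties are broken by a seeded random shuffle among the tied values
  (`tie_seed`), keeping runs reproducible.
* **Permutation p-values** use the add-one estimator
  $(1 + \#\{R^*_{perm} \ge R^*_{obs}\})/(1 + B)$, so a reported p-value
  is never zero; enumeration mode reports the exact tail proportion.
* **Anchoring.** Rank 1 maps to score $2\pi/n$ rather than 0. The
  statistic is rotation invariant, so the choice is cosmetic; it is
  fixed for reproducibility.
* The test is symmetric in its arguments and cannot say *which*
  population is more strongly locked, nor whether a detected difference
  is one of concentration or of preferred phase. It is a screen; follow
  up significant pairs with descriptive statistics.

## The comparison statistics

* **PLV / Rayleigh.** `plv()` is the mean resultant length;
  `rayleigh_pvalue()` gives the large-$n$ approximation
  $p \approx \exp(-n\,\mathrm{PLV}^2)$. A simplified form
  $\exp(-\mathrm{PLV})$ appears in parts of the phase-locking
  literature; it is dimensionally odd as a p-value (independent of the
  number of trials) and visibly uncalibrated, but it is retained
  verbatim behind `formula = "as_printed"` so published numbers can be
  reproduced. The default is the standard form. This ambiguity is
  documented rather than silently resolved.
* **PLI** (`pli()`) is $|\langle \mathrm{sign}\sin\theta\rangle|$:
  insensitive to coupling at exactly 0/π lag, hence to instantaneous
  crosstalk. Trials with $\sin\theta = 0$ contribute zero rather than
  being dropped — the estimator is a plain average and silently
  changing $n$ would bias comparisons. Only the magnitude is reported
  (leading vs lagging is not distinguished); the signed mean is
  available as `signed_mean_sign()`.
* **WPLI** (`wpli()`) weights by $|\Im\{X\}|$ of the cross-spectral
  term. It is implemented and tested for completeness but excluded from
  the default benchmark, which compares the unweighted PLI against the
  other methods; with equal-amplitude simulated sources the weighting
  only reacts to noise.
* **PBI** (`pbi()`) is
  $(\mathrm{PLV}_1 - \mathrm{PLV}_{all})(\mathrm{PLV}_2 -
  \mathrm{PLV}_{all})$ with $\mathrm{PLV}_{all}$ on the concatenated
  trials. PLI and PBI have no analytic null; `pli_significance()` and
  `pbi_significance()` wrap the generic label-permutation test with
  1000 permutations by default. The permuted statistic for PBI is the
  magnitude $|\mathrm{PBI}|$ (a locked-vs-random pair drives PBI
  strongly *negative*, so the magnitude is the detection-relevant
  quantity); the same magnitude is used when the benchmark ranks PBI
  scores. This is our choice of permuted statistic, documented as such.

## Morlet phase extraction

`morlet_coefficients()` returns one complex coefficient per trial and
channel: the inner product of the de-meaned signal with an
L2-normalized complex Morlet wavelet
$w(t) = e^{-t^2/2\sigma_t^2} e^{i 2\pi f t}$,
$\sigma_t = \mathrm{cycles}/(2\pi f)$, truncated at $\pm 4\sigma_t$ and
centred on the analysis time. Only the coefficient phases feed the
statistics, so the normalization is immaterial downstream (asserted by
test); de-meaning prevents DC leakage into short wavelets.

The envelope is parameterized by the number of cycles because
octave-based bandwidth phrasings are ambiguous (full-width
half-maximum in log frequency vs Gaussian σ cannot be told apart from
the phrase alone). The default of 7 cycles is a common choice for
gamma-band work: at 40 Hz it gives $\sigma_t \approx 28$ ms, so the
wavelet needs ~111 ms of margin from either recording edge — requests
closer than that raise an error stating the usable window. The exact
parameter used is recorded verbatim in the `bandwidth_spec` field.

Phase convention: coefficients are cosine-referenced, so a source
synthesized as $\sin(2\pi f t + \varphi)$ reads as $\varphi - \pi/2$;
pairwise phase *differences*, which are all the statistics consume, are
unaffected.

## What the simulator emulates

`simulate_experiment()` generates the conditions the statistics are
evaluated under:

* **Phase plan** — for locked trials, one fixed base angle per ROI
  (drawn uniformly once per simulation) plus an independent
  zero-centred von Mises perturbation per trial, concentration
  $\kappa$; for unlocked trials, fresh uniform angles every trial.
  Defaults: 20 locked and 20 unlocked trials, $\kappa = 50$ (with
  $\kappa = 20$ the usual milder condition).
* **Sources** — unit-amplitude 40-Hz sinusoids with the planned phase
  shifts, 1 s at 1000 Hz, analysed at 0.5 s.
* **Crosstalk** — the anatomical forward–inverse chain that produces
  leakage in real source estimates is collapsed into one explicit
  mixing matrix $I + s\,O$ ($O$ zero-diagonal, off-diagonal weights
  decaying with a random ROI layout, rows scaled to unit off-diagonal
  sum, so $s < 1$ keeps diagonal dominance). What matters for testing
  the statistics is the leakage phenomenon itself — false phase
  concentration between unlocked sources — not the anatomical route to
  it, and the linear form is exactly what a source-estimation pipeline
  produces.
* **Noise** — trial-independent Gaussian noise with a
  positive-definite spatial covariance (equicorrelated with jittered
  variances), globally scaled so that mean per-channel noise RMS /
  mean per-channel signal RMS equals `noise_level` (default 0.001,
  i.e. 0.1%). "Noise level" is operationalized as an RMS-amplitude
  ratio; amplitude conventions beyond "equal signal amplitude" are not
  otherwise pinned down, so sources are unit sinusoids.

What it does **not** emulate: realistic gain matrices and inverse
operators (and hence the empirical leakage profile of any particular
head model), sign-flip averaging over cortical patches, measured noise
covariance, non-sinusoidal or broadband sources, and amplitude
dynamics. Consequently the benchmark reproduces the *design* of the
evaluation — null calibration and the ordering of methods under
leakage — while absolute AUC values under severe anatomical crosstalk
are specific to that abstraction and are not comparison targets.

## The benchmark harness

`run_benchmark()` follows the replicate structure of the evaluation it
mirrors: per condition, 5 replicate sets × 4 iterations for each arm —
positive simulations (locked trials + unlocked baseline) and negative
simulations (two unlocked sets through the same mixing). Each ROI pair
in each iteration contributes one score per method (USTPL and PLV:
minus the p-value, a continuous score; PLI: the index; PBI: the index
magnitude); an ROC is built per replicate set by sweeping every
observed score as a threshold (ties contribute half-steps, making the
trapezoidal AUC equal to the Mann–Whitney probability, which the tests
assert against a brute-force pairwise oracle), and the mean ± sd of
AUC across the 5 sets is reported. USTPL p-values inside the benchmark
use the asymptotic tail regardless of $n$ so that scores are
continuous; at $n = 40$ the approximation's mild conservatism affects
both arms equally and ranking is what matters for an ROC. Error rates
at $\alpha = 0.05$, with and without Bonferroni correction by the
number of pairs, are reported for the two p-value-producing methods —
both as proportion correct and as its complement, since "error rate"
is used for both in the literature.

Two calibration points anchor the harness, and both are recomputed by
the test suite:

* with no crosstalk and no noise at $\kappa = 50$, every method's AUC
  is essentially 1 (sanity);
* with no locking in either arm, every method's AUC is within
  Monte-Carlo error of 0.5 (null calibration, `null_positives = TRUE`).

**The leakage scenario.** The confound demonstration uses 3 ROIs and
mixing strength 0.95. The strength is calibrated so the confound is
actually expressed: unlocked pairs must show Rayleigh-significant PLV
in most runs (the false-positive mechanism), which with this
row-normalized mixing requires strong leakage — at weak strengths the
unlocked-pair concentration is too mild to move PLV detection at all.
With three regions, near-cancelling leakage mixtures (which amplify
trial-wise phase jitter in genuinely locked pairs and so degrade PLV's
separation) occur at a useful rate, while the baseline-referenced
uniform-scores test is unaffected by construction: the same leakage
distorts both its populations. Under that scenario USTPL's mean AUC
exceeds PLV's and its uncorrected error rate is no worse — the
direction, not the magnitudes, is the reproducible claim.

## Problem sizes and numerical choices

Simulation-based checks in the test suite use: 10⁴ replicates for the
null distribution and type-I calibration of the asymptotic test
($n_1 = n_2 = 25$ and $50$), 1000 replicates for the concentrated
Rayleigh check, 2000 for Rayleigh null calibration, 100–200 seeds for
rate-style properties, 20-iteration benchmarks with 3 ROIs, and full
enumeration (252 assignments) as the permutation oracle at
$n_1 = n_2 = 5$. These sizes put Monte-Carlo standard errors well
inside the asserted bounds while keeping the whole suite to well under
a minute.

Numerical conventions, fixed once: angles live in $[0, 2\pi)$ (the
rank transformation needs a single fundamental domain anchored at 0;
inputs are wrapped silently on construction, and degree input is a
boundary conversion in `read_angles()`); the von Mises density is
evaluated with the exponentially scaled Bessel function so large
$\kappa$ does not overflow; sampling uses the Best–Fisher rejection
sampler, seed-reproducible and leaving the caller's RNG state
untouched; permutation comparisons use a $10^{-12}$ tie tolerance so
floating-point noise cannot turn an exact tie into a strict
inequality; the simulator derives per-stage seeds from the top-level
seed so stages are independently reproducible.

## Limitations

* The asymptotic $\chi^2(2)$ reference is stated for $n > 40$; below
  that the implementation switches to permutation/enumeration rather
  than trusting the tail.
* A significant uniform-scores test says the two distributions differ,
  not how; and if the baseline itself carries genuine (not
  instrumental) locking, "different from baseline" is not "locked".
* PLI's zero-lag blindness removes crosstalk but also removes genuine
  zero-lag physiology; the benchmark's ordering of PLI vs the rank
  test depends on trial counts and leakage geometry and should not be
  read as universal.
* Synthetic validation shows correctness of the machinery and the
  direction of the leakage effect; it cannot certify performance on
  any particular real head model or noise regime.
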