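---
title: "Methods: nonlinear HRV measures, paired statistics and the stress classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonlinear HRV measures, paired statistics and the stress classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hrvstress` analyses short-term (5-minute) RR-interval recordings with 13
nonlinear heart rate variability measures, compares paired rest/stress
sessions with the Wilcoxon signed-rank test, and builds linear discriminant
stress classifiers evaluated by subject-wise cross-validation. This
vignette is the package's own account of the methods: the models and their
assumptions, every tunable parameter with its default and rationale, the
numerical conventions adopted where the underlying definitions are
ambiguous, what the synthetic generator does and does not emulate, and the
known limitations. It states no empirical result that the package's tests
do not themselves compute.

## 1. Input model and reliability

The substrate is one session's RR-interval series in **seconds** with
per-beat labels. Non-normal (ectopic or artefactual) beats are **removed,
not interpolated**, leaving the normal-to-normal (NN) series; no gap
filling is attempted because every downstream measure operates on beat
index, not on continuous time. A record is *reliable* when its NN/RR ratio
(fraction of beats labelled normal) is at least 0.90; the exclusion rule is
"less than the threshold", so a ratio of exactly 0.90 is retained. A CLI
flag accepts milliseconds and divides by 1000; internally everything is
seconds. (Published tables of comparable analyses sometimes carry "ms"
column headers over values that are plainly seconds — e.g. an SD1 of 0.024
— which is why the package refuses to guess units from magnitudes.)

## 2. Conventions that every feature shares

* **Population standard deviation** (divide by N) for SDNN, SDDS, SD1 and
  SD2. One convention is applied globally because SDNN feeds every
  tolerance threshold (ApEn, recurrence radius), and the population form
  makes the Poincaré closed-form identities exact, which the test suite
  exploits (`SD1² = Var(ΔRR)/2` to 1e−12).
* **Delay embedding** `X_i = (x_i, x_{i+τ}, …, x_{i+(m−1)τ})` with τ = 1
  everywhere (the recurrence module exposes τ).
* **Tolerance comparisons**: ApEn and the correlation sum count `d ≤ r`
  (the classical Pincus counting); the recurrence matrix thresholds
  `d < r`, with a distance exactly equal to r mapped to 0. The two
  definitions come from different traditions and are deliberately not
  unified; both are frozen in tests.

## 3. The 13 measures

**Poincaré SD1/SD2.** Computed by the rotated-coordinate closed form:
SD1² and SD2² are the population variances of `(RR_{j+1} ∓ RR_j)/√2`. The
fitted ellipse often drawn over the return map is a visualization of the
same two numbers, not a separate estimator.

**Approximate entropy** (m = 2) at three tolerances, all reusing one pair
of max-norm template distance matrices per record (this is what makes the
81-point tolerance search affordable):

* `En02`: r = 0.2·SDNN, the classical recommendation for slow dynamics.
* `EnRmax`: r maximising ApEn over an evenly spaced 81-point grid on
  [0.1·SDNN, 0.9·SDNN] (step 0.01·SDNN, endpoints included), ties broken
  toward smaller r. The interval is standard; the grid is this package's
  choice, and a 10×-finer grid reproduces the argmax to within one coarse
  step on smooth profiles (tested).
* `EnRchon`: the regression tolerance
  `r_chon = (−0.036 + 0.26·√(SDDS/SDNN)) / (N/1000)^{1/4}`.
  **Design decision:** the formula's output is treated as a tolerance in
  SDNN units and applied as `r = r_chon·SDNN` (Chon's published usage).
  Applied literally as seconds it would exceed the whole dynamic range of
  a typical NN series (~0.2–0.3 s versus an SDNN of ~0.05 s) and drive
  ApEn to 0 identically — inconsistent with published values of En(r_chon)
  that track En(0.2·SDNN) closely. A `chon_mode = "literal"` override
  keeps the raw reading available, and the mode is recorded in the feature
  vector's metadata.

ApEn includes self-matches (so `C_i ≥ 1/(N−m+1)` and the logarithms are
always defined); a constant series yields exactly 0.

**Correlation dimension D2** (m = 10, Euclidean distances, self-pairs
included). The limit definition is approximated by the least-squares slope
of `log C^m(r)` on `log r`. Because no fitting range is canonical, the
package uses 50 log-spaced radii between the 1st and 99th percentiles of
the positive pairwise distances, restricted to the widest contiguous
sub-range with `C^m(r)` strictly inside `(1/K², 0.95)` — below the upper
bound the sum saturates, at the lower bound only self-pairs remain. The
fitted range is returned with every estimate. Negative slopes (possible on
very regular series) are clipped to 0. An all-equal embedding returns 0
directly (a point set has dimension 0).

**DFA.** The mean-centred series is integrated; for each box size
n = 4…64 the profile is split into ⌊N/n⌋ non-overlapping boxes (trailing
remainder dropped — forward partition only), linearly detrended per box,
and `F(n)` is the RMS residual over the covered ⌊N/n⌋·n samples. `alpha1`
is the log–log slope for n in [4, 16], `alpha2` for n in [16, 64];
**n = 16 belongs to both ranges**, as both printed ranges include it.
White noise yields α ≈ 0.5 and integrated white noise α ≈ 1.5 (both
verified by Monte-Carlo in the acceptance suite). A perfectly detrendable
profile (constant series) makes `F(n) = 0` and raises an estimation error
naming the offending box size.

**Recurrence quantification** (m = 10, τ = 1). The recurrence rate REC
sums the full K×K matrix including the line of identity (LOI), so
REC ≥ 1/K always. Diagonal lines are counted off the LOI only, with
minimum length 2; DET divides the line-covered points by the full-matrix
recurrence count; ShEn is the Shannon entropy of the line-length
distribution, computed on fractions with the natural logarithm and
**negated so that it is non-negative** (the raw `Σ n_l ln n_l` form is
non-positive for fractional `n_l`, while published ShEn values are ~3).
Consequence of these conventions, frozen in tests: a constant series gives
REC = 1 exactly and DET = (K² − K − 2)/K² — the LOI's K points and the two
corner length-1 diagonals sit on no counted line — which approaches the
idealised value 1 only as K grows.

**Radius.** The default is `r = √m·SDNN` (`rp_radius_mode = "sqrt_m"`),
the convention of the HRV software that popularised these RP measures.
The alternative literal reading `r = m·SDNN` is implemented
(`"literal"`) but near-saturates the matrix at m = 10 (REC → 1 for any
realistic series), flattening every line statistic; published REC values
around 30–40% are only consistent with the √m form. The mode used is
recorded in the result and in the pipeline run log.

## 4. Paired statistics

Descriptives are mean, SD (N−1 for descriptive tables), median and
quartiles (type-7 linear interpolation). Differences are
**stress − rest** per subject, so a negative median means the feature
decreased under stress. The signed-rank test discards zero differences
(Wilcoxon's original rule; Pratt's variant is not implemented),
average-ranks ties, and is **exact by full 2ⁿ sign enumeration for
n_eff ≤ 12** (two-sided p = 2·min of the tail probabilities, capped at 1);
above that, the normal approximation with tie correction and continuity
correction — verified identical to `stats::wilcox.test`'s approximation —
is used. The two branches agree to within 0.02 at the crossover (the
attainable bound: the true exact-vs-normal gap reaches ~0.014 at n = 12).
Sidedness and the zero/tie policy are choices recorded here, not claims
about any particular prior analysis; the test is two-sided because feature
shifts in both directions are of interest. P-values below 0.01 are
*displayed* as "<0.01" (numeric values are always kept alongside). No
multiple-testing correction is applied.

## 5. Classifier

Two-class LDA with **equal priors** (a paired design is balanced by
construction): weights `w = S⁻¹(μ_stress − μ_rest)` with S the pooled
within-class covariance, intercept placing the boundary at the midpoint of
the class means. The rule convention is `score = b + Σ w·x`,
**score > 0 ⇒ stress**, score exactly 0 ⇒ rest. A singular S (duplicated
or constant features) falls back to a ridge of 1e−8 on the diagonal with a
warning. Single-feature rules are additionally reported as directed scalar
thresholds ("stress if feature < t" when the stress mean is lower).

Cross-validation is **subject-wise**: subjects, not records, are randomly
partitioned into k = 10 folds whose sizes differ by at most one (42
subjects → eight folds of 4 and two of 5), so both records of a subject
are always tested together — person-independent testing. Metrics (ACC,
SEN, SPE, PPV, NPV, stress positive) are averaged unweighted over folds;
folds where PPV or NPV is undefined (no predicted positives/negatives) are
excluded from that metric's average with the exclusion count reported,
never silently zeroed. Whether to average per-fold metrics or pool
confusion counts is not canonical; per-fold averaging is implemented as
the primary route.

The exhaustive search enumerates all 2¹³ = 8192 subsets, evaluates the
8191 non-empty ones (an empty-subset classifier is undefined; both counts
are reported) under **one shared fold assignment** so rankings are
comparable, and ranks by averaged ACC with ties broken toward fewer
features, then higher SEN, then lexicographic subset order (the primary
criterion is standard; the tie-break chain is this package's choice).
Internally the search reuses per-fold class means and pooled covariances
of the full feature matrix — each subset solves the corresponding
submatrix — which the tests verify reproduces `cross_validate()` exactly.
The final reported rule is refit on the whole dataset (cross-validation
only estimates its performance).

## 6. The synthetic generator: what it emulates and what a green test means

Each record is
`RR_i = mean_rr + A_LF·sin(2π·0.1·t_i + φ₁) + A_HF·sin(2π·0.25·t_i + φ₂) + z_i`
with `z` an AR(1) process, beats appended until 300 s are covered, 1% of
beats marked ectopic with a ±30% perturbation. Defaults (rest vs stress):
mean RR 0.85 vs 0.70 s; LF amplitude 0.04 vs 0.015 s; HF amplitude 0.02 s;
AR coefficient 0.3 vs 0.8 with innovation sd 0.02 vs 0.008 s; 15%
log-normal between-subject jitter on all amplitudes, with phases and
jitter shared between a subject's sessions so within-subject pairing is
real. Streams are counter-split from one master seed, so adding subjects
never perturbs existing ones. A hard floor of 0.05 s guards interval
positivity (never active at default scales). These values are a stated
world: sinusoid-plus-AR(1) is the simplest model with separately tunable
long-term spread (LF amplitude → SD2), regularity (AR coefficient,
innovation sd → entropy, recurrence) and scaling (→ DFA); it is **not** a
physiologic simulator — no integral pulse frequency modulation, no
respiratory sinus arrhythmia coupling, no non-stationarity, no circadian
or postural effects.

Measured consequence (10 default cohorts of 42 subjects; computed by the
acceptance suite, not asserted from memory): stress−rest shifts are
robustly negative for SD2, D2, En(r_chon) and alpha1 — with the SD2
signed-rank p below 0.01 on every seed — and the {SD1, SD2, En02}
classifier far exceeds the shuffled-label null accuracy of ~0.5. But
**En02 shifts positive** (the rest session's large deterministic LF
oscillation is *more* ApEn-regular at r = 0.2·SDNN than the stress AR(1)
dynamics, whereas the Chon tolerance adapts via SDDS/SDNN and does
reproduce the decrease), **lmax shifts positive** (stress records contain
~20% more beats and more recurrent dynamics, lengthening the longest
line), and REC/lmean/ShEn are inconsistent across seeds. The corresponding
acceptance expectations are left failing rather than the generator being
tuned after measurement: a green direction test here establishes only that
the pipeline propagates the generator's stated physiology, and the
generator's stated physiology only partly matches what real stressed
hearts do.

## 7. Degenerate inputs and numerical edges

Constant series: SD1 = SD2 = 0; ApEn = 0 exactly; SDNN = 0 makes every
SDNN-derived tolerance undefined (error); DFA errors (F(n) = 0); D2
returns 0. Fewer than 2 normal beats after filtering, thresholds outside
[0, 1], non-positive tolerances, missing sessions, and k exceeding the
subject count all raise validation errors before computation. All
stochastic behaviour (folds, generator) flows through explicitly passed
seeds with save/restore of the caller's RNG state.

## 8. Known limitations

* Feature computation is O(N²) per record in memory and time — fine for
  5-minute series (N ≲ 500), not intended for 24-hour Holter records.
* The exhaustive search refits 8191 × k classifiers; with the
  moment-reuse path this is seconds for 13 features, but the cost doubles
  per extra feature.
* The Wilcoxon normal approximation is used above n_eff = 12; for cohorts
  in between, the exact branch can be forced via `exact_max`.
* No frequency- or time-domain (linear) HRV measures, no surrogate-data
  testing, no nonlinear classifiers (ANN/SVM) — deliberately out of scope.
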