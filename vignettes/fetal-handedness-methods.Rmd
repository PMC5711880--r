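---
title: "Inferring postnatal handedness from fetal arm-movement kinematics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring postnatal handedness from fetal arm-movement kinematics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalhand)
```

## The problem

Most humans become right-handed, and lateralized fetal arm movements are
visible on ultrasound from early gestation. The question this package's
pipeline addresses is whether the *kinematics* of those movements — not just
how often each hand is used — already carry the individual's future
handedness. The design it serves observes fetuses longitudinally at
gestational weeks (GW) 14, 18 and 22, tracks wrist trajectories at 4 Hz
during reaches toward three targets of decreasing precision demand (eye,
mouth, uterine wall), and compares the two hands within each fetus. The
postnatal criterion is the hand the child writes with at age 9.

Two kinematic features summarise each movement:

* **MT** (movement time, ms): onset of the reach to its stable ending on the
  target.
* **TPV** (time-to-peak-velocity, % of MT): when speed peaks and
  deceleration begins. A *larger* TPV means a *shorter* deceleration phase.

## The statistical model

### Why differences, not raw values

Overall movement speed is a property of the fetus: the per-fetus right-hand
and left-hand MT means are strongly correlated (the package's
`within_subject_correlation()`; the generator reproduces medians near 0.9).
Raw between-group comparisons therefore mix a large shared "fetus speed"
component with the small lateralized signal. The **hand-asymmetry
advantage** removes it by differencing within fetus:

$$\mathrm{HAA} = \overline{\mathrm{RH}} - \overline{\mathrm{LH}}, \qquad
\mathrm{rHAA} = \frac{2(\overline{\mathrm{RH}} - \overline{\mathrm{LH}})}
{\overline{\mathrm{RH}} + \overline{\mathrm{LH}}},$$

per fetus, week, and target. For MT, the dominant hand is the faster one, so
$\mathrm{HAA}_{MT} < 0$ predicts right-handedness; for TPV the dominant hand
peaks later, so $\mathrm{HAA}_{TPV} > 0$ predicts right-handedness
(`sign_classify()`). A zero HAA is scored as an error against either label —
a conservative, configurable tie policy.

### Robust primitives

The data are small, skewed, and unbalanced (25 right- vs 4 left-handed
fetuses; uneven per-condition counts), so the pipeline avoids Gaussian
machinery throughout:

* `hodges_lehmann(x, y)`: median of all cross-sample pairwise differences —
  the location-shift effect size.
* `welch_u_test(x, y)`: Welch's unequal-variance *t* applied to pooled
  mid-ranks (the rank-transform construction), a test of stochastic
  dominance without normality or homoscedasticity assumptions.
* `benjamini_hochberg()`: step-up FDR control across each family of
  comparisons (the family is all conditions of one metric — the most
  conservative reading consistent with reporting significance per metric).
* `binomial_test()`: exact, two-sided by the minimum-likelihood rule —
  appropriate at per-group counts of a few dozen movements.
* Ties receive mid-ranks everywhere.

### Classification and its significance

`permutation_accuracy_test()` shuffles the handedness labels uniformly and
recomputes the sign-rule accuracy; the p-value is the fraction of
permutations whose accuracy *strictly exceeds* the observed one. That
literal rule is the package default for faithfulness to the procedure it
reimplements. It has a real statistical cost: with 4 minority labels the
permutation accuracy distribution has only about five atoms, and observing
the top atom (probability ≈ 0.05–0.5 depending on the prediction
composition) forces p = 0. Under a true null this rejects far above nominal
(≈ 0.13–0.20 measured at α = 0.05). `include_ties = TRUE` switches to
P(accuracy ≥ observed), the standard conservative-valid rule (measured
rejection ≤ 0.01 in the same worlds); `smooth = TRUE` gives the
add-one-smoothed variant. The acceptance suite asserts the stated
[0.02, 0.10] band for the literal rule and documents its failure rather
than silently substituting the valid rule.

`group_haa_separation()` complements the sign rule with magnitude: the
Hodges-Lehmann difference between the left-handed and right-handed groups'
HAA distributions (oriented left-minus-right so an MT effect is positive),
tested with the Welch U-test.

`silhouette_analysis()` uses the variant in which the between-cluster term
is the *minimum* distance to the other cluster (not the classical mean).
One consequence worth knowing: under exchangeable (null) data the mean
silhouette is not 0 but about −0.73, because a minimum is systematically
smaller than a mean; positive values therefore indicate strong clustering.

`loocv_logistic()` fits, for each held-out fetus, a logistic regression of
handedness on the features (per-fetus RH and LH means, or a 1-D rHAA) and
predicts at threshold 0.5, letting the decision boundary leave the identity
line. A negligible ridge penalty (λ = 1e-6 on standardised features) keeps
the Newton solver finite under complete separation; with saturated
predictions this is a numerical device, not a model change. Single-class
training folds fall back to majority prediction.

### Development

`mt_trend()` is the Spearman correlation between all pooled MT values for a
target and GW. `binned_mutual_information()` discretises MT into 8
equipopulated bins (ties broken by value order; equal-width bins available)
and computes plug-in MI in bits, minus the first-order Panzeri–Treves bias
estimate $\frac{1}{2N\ln 2}\left[\sum_g (\tilde B_g - 1) - (\tilde B -
1)\right]$ with $\tilde B_g$ the naively counted occupied bins. The bias
term is positive in the independence regime it is designed for and the
corrected estimator is then approximately unbiased (mean within
[−0.02, 0.04] bits at N = 150); for strongly dependent data the term can
legitimately be negative, so the package does not clamp it. MI significance
is by group-label permutation (strictly-greater rule; method otherwise
unspecified in the source procedure).

A binning subtlety: three equal groups can never align with 8 equal-count
bins (group size N/3 is never a multiple of bin size N/8), so a
deterministic 3-group structure reaches exactly log2 3 bits only with
equal-width bins over well-separated ranges, or with equipopulated bins
whose size divides the group size (e.g. 6 bins with 8 samples per group).
Both routes are tested.

## The synthetic cohort generator

`generate_cohort()` draws the stated world of the analysis:

| parameter | default | meaning |
|---|---|---|
| `n_fetuses`, `p_right` | 29, 25/29 | roster; by default exactly 25 right-handers (fixed composition) |
| `mu_mt` | eye 900/1100/1300, mouth 1000, wall 800 ms | baseline MT per target × week (implementer defaults; no per-target means are published) |
| `delta_mt` | 318 ms, eye & mouth, GW ≥ 18 | dominant-hand MT advantage, split −δ/2 / +δ/2 between hands |
| `delta_tpv` | 2.1 pp, eye & mouth, GW ≥ 18 | dominant-hand TPV advantage |
| `sigma_fetus` / `sigma_resid` | 450 / 300 ms | between-fetus shared offset vs within-fetus residual |
| `sigma_tpv` | 5 pp | TPV residual |
| `rh_use_prob` | RH-group .55/.60/.60; LH-group .50/.45/.45 | right-hand-use probability per group × week |
| `movements_per_fetus_week` | 139/29, 164/29, 185/29 | Poisson means matching the published week totals in expectation |
| `mt_floor` | 200 ms | lower truncation (injects mild non-normality) |

Design choices made where the design was genuinely open:

* **±δ/2 split.** Assigning −δ/2 to the dominant and +δ/2 to the
  non-dominant hand leaves every condition mean independent of the
  handedness composition, so the asymmetry lands entirely in the HAA. The
  group HAA distributions then centre at −δ (right-handers) and +δ
  (left-handers), and the left-minus-right separation is 2δ ≈ 636 ms.
* **Fixed 25/4 composition.** Independent Bernoulli(25/29) draws produce
  0–3 left-handers in roughly a third of cohorts, which leaves group
  comparisons undefined and makes the permutation atoms even coarser; the
  cohort being emulated has a fixed 25/4 roster. `handedness_assignment =
  "bernoulli"` restores independent draws.
* **Additive Gaussian MT with a floor** (lognormal residuals behind a
  flag): the target effect is additive (318 ms), and truncation at 200 ms
  adds the mild non-normality the analysis must tolerate. Note the floor is
  *not* rare at these parameters: with total SD ≈ 541 ms against baselines
  of 800–1300 ms, ≈ 8% of movements are floored (the count is logged as an
  attribute). This censoring slightly attenuates within-subject
  correlations.
* **Movement counts: two irreconcilable stated values.** The published
  week-by-group totals imply ≈ 1 movement per hand × target × week cell,
  while the parameter-recovery statements assume ≈ 4 movements per hand and
  condition. The generator default follows the published totals; recovery
  tests and the acceptance parameter-recovery criterion run at
  `movements_per_fetus_week = 24` (≈ 4/hand/condition), where the
  closed-form expected sign accuracy at (eye, GW18) is ≈ 0.93 rather than
  ≈ 0.80. Both worlds are exercised in the test suite.

### What a green test does and does not establish

The generator reproduces the *statistical skeleton* the analysis assumes:
shared per-fetus speed offsets, a symmetric dominant-hand shift, published
count marginals, handedness-dependent hand-use rates. It does not model
biomechanics, fetal position, target-specific movement shapes, serial
correlation within a session, or measurement error in manual wrist marking.
A green parameter-recovery test establishes that the pipeline recovers
effects from data satisfying its own assumptions — not that the assumptions
hold in utero.

Closed-form check used by the tests: the within-subject correlation between
per-fetus hand means is
$r = (\sigma_b^2 - v_h)\,/\,\sqrt{(\sigma_b^2 + v_h +
\sigma_e^2/m_{RH})(\sigma_b^2 + v_h + \sigma_e^2/m_{LH})}$ with
$v_h = (\delta^2/4)\,\mathrm{var}(h)$ the variance contributed by the ±δ/2
displacement across fetuses of mixed handedness and $m$ the harmonic-mean
number of movements averaged per hand (`expected_within_subject_r()`). At
σ_b = 450, σ_e = 300, m = 4 and δ = 0 this is exactly 0.9.

## Kinematics extraction

`speed_profile()` differentiates the calibrated 2-D track with central
differences (second-order accuracy matters at 4 Hz); ends use one-sided
differences; no smoothing by default (a 3-point moving average sits behind
a flag). `detect_bounds()` applies a 5%-of-peak threshold with a
two-sample below-threshold requirement for the offset — the onset/offset
rule is unspecified in the source procedure, so this standard convention is
a documented substitute, exposed in the interface. `extract_metrics()`
searches the speed peak strictly after the onset sample so TPV ∈ (0, 100].

Recovery accuracy on noiseless synthetic trajectories: one 4 Hz sample
period (250 ms) per *detectable* boundary. With steep speed shoulders
(TPV ≈ 50) the total MT error stays within one sample period; with shallow
shoulders (long movements at low TPV) the 5% crossing can fall one sample
inside at *each* boundary, so the honest worst-case bound is two sample
periods. Both bounds are asserted in the tests.

## Numerical and degenerate-input policy

* All pooled values identical → Welch statistic 0, p = 1; constant samples
  → correlations flagged `NA` with a warning.
* Conditions with fewer than 2 movements (comparisons) or 2 fetuses per
  group (separation, silhouette) are reported untested, never fatal.
* Exact Wilcoxon enumeration up to 40 000 subsets, normal approximation
  with tie and continuity corrections beyond.
* Permutation seeds: every pipeline stage derives its own sub-seed
  deterministically from the master seed, so report bundles are
  byte-identical across reruns.

## Known limitations

* The literal strictly-greater permutation rule is anti-conservative at
  4 minority labels (see above); use `include_ties = TRUE` when validity
  matters more than procedural faithfulness.
* The developmental trend the default generator produces for the eye
  target is ρ ≈ 0.28, weaker than the ≈ 0.47 reported on real data — the
  450 ms between-fetus SD attenuates the 200 ms/week signal. The baselines
  are kept as stated rather than tuned.
* Per-target movement counts are not recoverable from the published
  marginals; the generator assigns targets uniformly.
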