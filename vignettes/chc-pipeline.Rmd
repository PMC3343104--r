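---
title: "Models and methods behind the flychc pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the flychc pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flychc)
```

This vignette documents the statistical models the package implements, the
assumptions behind them, the defaults of the synthetic-data generators, and
the numerical conventions adopted where several defensible choices existed.
It is the reference for *why* the code does what it does; the README shows
*how* to run it.

## 1. Relative quantitation of CHC profiles

Neither GC/MS chromatographic peak intensities nor LDI-MS ion signal
intensities measure absolute compound amounts: detection efficiency is
compound-dependent, and LDI-MS signals additionally depend on the position
of the fly relative to the laser. The pipeline therefore works exclusively
with relative profiles: each identified hydrocarbon's intensity is divided
by the per-sample sum over all identified hydrocarbons. Two consequences
shape everything downstream:

* **Per-sample factors cancel exactly.** Any multiplicative factor common
  to a sample (amount of cuticle extracted, laser position, injection
  volume) divides out. This is the scale-invariance property asserted in
  the tests.
* **Per-compound factors do not cancel, but become constant.** A
  compound-specific detection efficiency multiplies that compound's
  normalized share by the same factor in every sample, so *contrasts*
  between genotypes or ages are unaffected. Absolute shares remain
  unrecoverable, which is why the package never reports them as amounts.

Compounds not flagged `is_identified_hydrocarbon` are excluded from the
denominator and dropped. Oxygenated compounds that co-occur with the CHC
profile (e.g. `C27H54O2`) are treated as identified by default because they
are part of the measured profile; `compound_descriptors(...,
oxygenated_identified = FALSE)` excludes them, and both choices are
exercised in tests.

**Pseudo-count before the log.** Per-compound statistics run on the
natural-log scale, where multiplicative biology becomes additive and model
residuals are approximately normal. Zeros (chromatographic non-detections,
treated as true absence rather than missing-at-random) would map to
−∞, so when a table contains any zero the transform is
`ln(x + eps)` with `eps` = half the smallest positive normalized intensity
in the table; when there are no zeros `eps = 0` and the transform is a
plain log (so a normalized intensity of exactly 1 maps to exactly 0). The
`eps` used is recorded in the table's `ln_epsilon` attribute so a run is
auditable.

## 2. Per-compound ANOVA, Holm correction, chance accounting

Each compound gets `ln intensity ~ genotype * age` with both factors
categorical. Sums of squares are **Type II** (`car::Anova`): no published
convention distinguishes the types on balanced data, and
synthetic fixtures are balanced, so the tests are convention-proof; Type II
is the sensible default for the mildly unbalanced designs real data
produce (it tests each main effect after the other, without assuming the
interaction). Compounds with zero residual degrees of freedom are flagged,
get `NA` p-values, and are excluded from the multiplicity correction.

Holm's step-down is implemented directly (ascending p, threshold
`alpha/(m - k + 1)`, stop at first failure) because the per-rank thresholds
are part of the reported result; it is cross-checked against
`stats::p.adjust(, "holm")` on random vectors in the tests. The expected
number of chance rejections among `m` independent null tests is `m * alpha`
(1.3 for a 26-compound panel at α = 0.05) — reported so the observed count
of significant compounds can be read against it.

Outliers are never removed automatically. An explicit `(compound,
sample_id)` exclusion list reruns the analysis without the flagged points,
so a "remove and reanalyze" robustness check is visible in code.

## 3. Delta profiles, chain-length regression, PCA + ANCOVA

The per-compound effect of a manipulation is the difference in mean
normalized intensity (and its percent change) relative to the control.
When the two genotypes were measured at several shared ages, the group
mean is the **unweighted mean of per-age means** — the ANOVA main effect
under equal cell weights — rather than a pooled mean that would let an
unbalanced age distribution masquerade as a genotype effect; the published
convention is not stated, so ours is documented here and enforced by a
precondition that both groups share the same ages. Percent change is
flagged undefined where the control mean is zero.

Chain-length structure is tested by OLS of percent change on carbon count
(two-sided slope p). Note the caveat that compounds are not independent
(shared biosynthesis), so these p-values can be liberal; the package
reports them as screening statistics. Carbon counts come from the compound
grammar: methyl-branched alkanes count the methyl carbon (2-MeC26 → 27
carbons), dienes and positional monoenes resolve chain length through an
alias table (7-T → C23, 7,11-HD → C27, 7,11-ND → C29).

PCA is computed on **correlations** (compounds standardized to unit
variance) so abundant compounds do not dominate; zero-variance compounds
are dropped with a message. Whether to feed normalized or ln-normalized
intensities is genuinely open; both are accepted and the examples use the
ln scale, consistent with the ANOVA arm. Each retained component is then
modeled as `score ~ genotype * age` with age continuous. The genotype and
age p-values are Type II; the interaction p is reported separately because
"aging moves both genotypes in parallel" is exactly the claim that a
non-significant interaction (with significant main effects) supports. The
genotype effect estimate reported is the coefficient of the additive model
— the age-adjusted between-genotype shift — which is well-defined for the
two-level comparisons the pipeline targets.

## 4. Two-choice preference

**Dwell scoring.** A frame counts toward a target when the male's position
is within the 3 mm scoring circle, boundary inclusive (`distance <=
radius`); ties on the boundary are so rare in real data that the convention
matters only for reproducibility. Dwell time is frame count over frame
rate, so `t_A + t_B + t_outside = frames_used / fps` exactly. Frames with
missing coordinates are dropped from numerator and denominator and logged.
Circles that would overlap (separation ≤ 2 r) make a trial unusable —
dwell near one target could not be attributed.

**Exclusion rule.** Preference is `100 · t_manip / (t_manip + t_ctrl)`.
Trials with total target time strictly below 50 s are removed (a male that
never engaged provides no choice information); exactly 50 s is kept. Over
a 30-min observation the threshold is 2.8 % of the recording, a number the
package computes rather than hard-codes (`exclusion_threshold_pct()`).
Courtship bout lists keep bouts **strictly longer** than 20 s (a 20.0 s
bout is discarded) and apply no minimum-total rule — the live assay
defines none.

**Wilcoxon.** The one-sample signed-rank test against 50 % drops exact
zeros, uses the exact distribution for n ≤ 25 when the absolute
differences are tie-free, and otherwise the normal approximation with
continuity correction; the method actually used is reported.

**Stratified permutation test.** Trials pooled across replicates are
tested by randomizing treatment labels and recomputing the pooled
statistic (mean preference over kept trials by default; median by flag)
for each of 30,000 randomizations, all pooled into one null distribution.
The default scheme flips each trial's two labels independently with
probability 1/2 (preference p ↦ 100 − p), which preserves the paired
two-choice design and — since every trial lives inside one replicate —
automatically confines randomization within replicates. The phrase
"labels randomized among flies within a replicate" admits a looser
reading, so a `pooled_within_replicate` scheme (pool a replicate's dwell
times, relabel and re-pair them, re-apply the kept rule) is provided; the
default is the conservative pairing-preserving scheme, and we do not claim
either is the historically exact one. Tail probabilities use the add-one
rule `(1 + #extreme)/(n + 1)` with ties counted as extreme, guaranteeing a
valid p in (0, 1]; the exhaustive-enumeration oracle in the tests uses raw
proportions, and the two agree within Monte-Carlo error on every ≤12-trial
fixture. The two-sided p is `min(1, 2 · min(tails))`.

## 5. Relative expression (ΔΔCT)

Technical replicates are averaged to one Ct per (condition, extraction,
gene) — the natural reading of "replicate reactions per extraction" — then
ΔCT = Ct_gene − Ct_ref, ΔΔCT = ΔCT_manip − ΔCT_ctrl, fold change 2^−ΔΔCT,
ln fold change = −ΔΔCT·ln 2. Because every quantity is a within-sample
difference, a global Ct shift cancels (tested). Biological replicates are
paired by label when both conditions share labels; otherwise each
manipulated extraction is compared against the mean control ΔCT (both
modes are available explicitly). The test of no change is a **z-test**
over biological replicates — mean/(sd/√n) against the standard normal —
which is anticonservative at n = 3; a t-variant is available behind
`use_t = TRUE` but is not the default, since the z-test is the assay's
conventional choice and the error bars reported are the replicate SEs
either way.

## 6. The synthetic-data generators

The generators define the conditions under which the pipeline is
validated; their defaults are fixed once and the calibration/recovery
tests run against them.

**CHC tables** (`chc_sim_config`): ln-normal intensities,
`ln raw = ln eff_j + ln base_j + g·(beta_j + gamma·(c_j − c̄)) + delta·age
+ N(0, sigma)`. Defaults: 26 compounds spanning C21–C29 (alkane, monoene,
diene and methyl-branched form per chain length), genotypes control vs
mutant, ages 6/23/37/48 d, 5 replicates per cell, σ = 0.3 on the ln scale
(≈ 30 % biological CV, typical for quantitative MS of biological
extracts), all effect sizes 0 (a null table) unless injected. Baselines
and detection efficiencies are drawn log-normally from the seed and
returned as ground truth. The chain-length term is centered on the middle
of the carbon range so it injects a profile *tilt* rather than a uniform
shift — a uniform ln-scale shift of all compounds cancels in normalization
and is deliberately unrecoverable. Positional (LDI-MS) variability has no
stated distribution; it is a per-sample multiplicative factor, which
normalization removes, so it is folded into the per-sample noise rather
than modeled separately.

**Trajectories** (`trial_sim_config`): a discrete-time two-state process —
geometric-length wandering and visiting bouts (mean visit 5 s; the
wander/visit split set by `dwell_fraction`, default 0.3) with each visit
allocated to the manipulated target with probability
`true_preference_pct/100`. Only dwell times carry information in the
analysis, so no physical walk is modeled: wandering frames are uniform in
the arena outside both circles, visiting frames uniform inside the chosen
circle. The default arena is a 55 mm dish with targets 18 mm apart and
8.5 mm from the wall; these two constraints are incompatible with
diametrically opposed targets, so both targets sit 19 mm from the center
on a chord. `generate_trial_set()` emits full trajectories;
`simulate_trial_scores()` runs the identical bout process without
positions for large simulation studies, and the two are cross-checked for
distributional agreement in the tests. What the generator does *not*
emulate: courtship micro-behavior, wall-following, temporal
non-stationarity, or tracking noise — so passing recovery tests show the
*scoring and inference machinery* is correct, not that real fly behavior
matches a two-state walk.

**Ct tables** (`ct_sim_config`): `Ct = baseline_ct − ln(expr)/ln 2 +
N(0, sd)` per technical reaction (default sd 0.15 cycles, a typical SYBR
precision), defaults 3 biological × 5 technical replicates, reference gene
forced to fold change 0. Between-extraction variability arises from the
averaged technical noise; real extraction-to-extraction biology would add
variance, which is why the recovery tests use the replicate-based CI
rather than a theoretical one.

All generators take one explicit seed and are byte-reproducible under it.

## 7. Problem sizes and tolerances in the test suite

The suite validates calibration and recovery at sizes chosen to make the
Monte-Carlo error small relative to the assertion while keeping a full run
fast: 500 null experiments of 12 trials for the preference tests
(rejection bounded by α + 2·SE), 1000 null tables of 4 compounds for the
ANOVA calibration and KS-uniformity check, 20 replicate simulations for
slope recovery (power > 0.9 asserted), and 30,000 randomizations wherever
the permutation test runs, matching its default. Exhaustive enumeration
oracles are used up to 12 trials (2¹² flip patterns). Numerical
tolerances: normalization sums to 1 within 1e−9; ANOVA agrees with the
explicit sums-of-squares oracle within 1e−8; identities (label swap,
mirroring, Ct shifts) within 1e−12.

## 8. Known limitations

* Per-compound tests ignore the compositional dependence that
  normalization induces (shares sum to 1); with 26 compounds the induced
  negative correlation is small but the family of p-values is not strictly
  independent, and chain-length regression p-values inherit the same
  caveat.
* The permutation scheme ambiguity (§4) is resolved by a documented
  default, not by evidence about the original implementation.
* The z-test at n = 3 biological replicates is anticonservative; use
  `use_t = TRUE` for honest small-sample inference.
* The pipeline consumes trajectories and bout lists; video tracking and
  bout annotation are upstream and out of scope, as are peak picking and
  compound identification for the MS tables.
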