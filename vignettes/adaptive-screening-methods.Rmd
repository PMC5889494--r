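---
title: "Adaptive diagnostic screening: models, rules, and reliability methods"
author: "adaptscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive diagnostic screening: models, rules, and reliability methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptscreen)
```

## The screening model

The package implements a two-stage, criterion-counting model of
self-report diagnostic screening. An always-administered **screener**
covers 13 diagnostic categories with 65 items; each category's module
carries a *threshold rule* over its screener items, and a respondent who
satisfies it "screens in" and receives that module's **follow-up**
section. Follow-up responses feed diagnosis-agnostic symptom
**criteria**, and symptom-counting **diagnosis rules** (at least *m* of
*n* criteria, at least one cardinal) assemble the differential
diagnosis. The underlying assumptions:

* *Frequency is severity.* A five-level frequency scale (never, rarely,
  sometimes, often, always) carries the signal; a symptom "counts"
  toward a criterion at often/always (never/rarely for reverse-scored
  items). This endorsement mapping is the empirically calibrated bridge
  between self-report frequencies and clinician symptom judgments, and
  everything downstream is deliberately binary at the criterion level.
* *Screen sensitive, diagnose specific.* Screen-in thresholds sit a
  full level below the endorsement level (at least *sometimes* by
  default), so the follow-up gate is more sensitive than the diagnosis
  rules operating on endorsements. One published exception is encoded:
  the "I felt sad" screener over-included at *sometimes* and is raised
  to *often*. A structural consequence, enforced by construction in the
  packaged instrument and property-tested over random complete response
  vectors, is that any respondent who could satisfy a diagnosis rule
  would also have screened in: every rule's cardinal subset maps only to
  screener items, at endorsement thresholds no looser than screen-in.
* *Concurrency by anchoring, not arithmetic.* The "same 2-week period"
  style windows are realized the way the instrument itself realizes
  them: follow-up items carry a lead prompt anchoring them to the
  episode the respondent screened in on ("During the time(s) when I felt
  anxious…"). `window_days` is retained as rule metadata; no date
  arithmetic is performed.

## The packaged fixture instrument

The shipped instrument reproduces the published structure exactly — 65
screener items over 13 modules, a 28-entry diagnosis catalog, six
depression screeners (two reverse-scored), four yes/no trauma-exposure
screeners, single yes/no panic/cannabis/other-substance screeners, a
30-day drinking-days count — while the item *texts* beyond the published
examples are authored here from DSM-5 symptom labels in the same style
rules (single concept, no idioms, simple words). They are serviceable
stand-ins, not the validated items, and the follow-up pools (2–13 per
module) are the minimum needed to cover every criterion rather than the
full development item bank.

Decisions where the published record is silent, all configurable in the
instrument file:

* **Non-depression screen-in thresholds** default to the sensitive
  "at least sometimes" level, the stated design intent for screening.
* **Alcohol** screens in at ≥ 5 drinking days in 30; the same cut is
  the item's endorsement cut, which keeps screen/diagnose consistency
  exact for the count scale.
* **Catalog composition.** The catalog carries the three current mood
  episodes and 25 disorders. The bipolar-course diagnoses are excluded:
  assembling them requires past-episode history, which the instrument
  does not yet collect; the episode rules' notes describe the
  composition (a manic episode plus history composes bipolar I, a
  hypomanic episode plus a major depressive episode composes
  bipolar II).
* **Rule algebra limits.** A rule is *m*-of-*n* with one
  at-least-one-of cardinal subset. That algebra cannot *conjoin* two
  required criteria, so the seven other-substance diagnoses key their
  cardinal on the module's use screener while the per-substance identity
  criteria only count toward *m*; sibling substance diagnoses can
  therefore co-appear in the differential and the clinician
  disambiguates. Exclusion criteria ("not better explained by…") live in
  rule notes and are never machine-evaluated.
* **Screener-internal branching** is represented by the one published
  mechanism: the four trauma-exposure questions gate the PTSD symptom
  items. All 65 screener items are otherwise unconditional, so a session
  always starts with the full screener pending.

## Sessions, missing data, determinism

Item order is fixed (no randomization) for reproducibility. Sessions
are resumable; the screen-in map is computed only when the screener is
complete, and scoring treats modules with unanswered items as
*incomplete* — they are listed in the report and never silently scored.
Identical response scripts always produce identical item sequences and
reports.

## Reliability methods

**ICC.** Summary scores (Likert levels summed, reverse items as
6 − value) are compared across occasions with the single-measure,
absolute-agreement intraclass correlation from the two-way ANOVA
decomposition — the model appropriate when the same respondent
self-reports at test and retest, so occasion is a systematic factor and
absolute agreement (not mere consistency) is the target:

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}, \quad k = 2.$$

The null of zero reliability is tested with $F = MS_R/MS_E$ on
$(n-1,\,(n-1)(k-1))$ degrees of freedom, and the two-sided 95% CI uses
the F-distribution interval with Satterthwaite degrees of freedom — a
declared choice, since only "two-tailed 95% CIs" is on record for this
design. Degenerate inputs (no variance anywhere) yield a
`not_analyzable` result, not an error.

**Log transform.** Strongly right-skewed score distributions (sample
skewness > 1 — in practice the agoraphobia domain, which hugs the scale
floor in nonclinical samples) are transformed by
$x \mapsto \log(x - \mathrm{floor} + 1)$ before the ICC, so a
floor-valued score maps to zero. The offset (+1 after shifting to a
zero floor) is a declared choice.

**Kappa.** Categorical screeners use Cohen's
$\kappa = (p_o - p_e)/(1 - p_e)$, with a two-sided p-value from the
large-sample (Fleiss) standard error under independence, and a
percentile bootstrap 95% CI over B = 2000 respondent-level resamples
(percentile method and B are declared choices). Two degeneracy rules
matter in small samples:

* `cohen_kappa` itself is mathematical: only a constant column (an
  empty cell making κ undefined) is `not_analyzable`.
* In the module table, a category carried by fewer than **two**
  respondents is reported `not_analyzable` even though κ is formally
  defined (a single stable endorser gives κ = 1 with no supporting
  information — the published judgment for the other-substance module).
* A bootstrap interval is reported *unavailable* when more than 25% of
  resamples are degenerate. The limit is deliberate: under respondent
  resampling a lone endorser is excluded with probability
  $\approx e^{-1} \approx 37\%$ while two or more endorsers fall below
  15%, so 25% cleanly separates "too rare to bootstrap" from
  analyzable data. (A majority rule could never fire: data with a
  defined κ always retain at least one endorser, capping degeneracy at
  37%.)

Percentile bootstrap intervals at n = 42 are known to run slightly
anti-conservative; in simulation their empirical coverage sits around
92–96% against the nominal 95%, while the ICC F-interval is essentially
nominal. The banding rule classifies coefficients below .60 as fair,
from .60 up to the selectable high cut (.75 default, .80 selectable) as
good, and above it as excellent.

**Diagnostics.** `screening_consistency()` counts both/one/neither
screen-ins per module across occasions and identifies items solely
responsible for single-occasion screen-ins — the analysis that isolated
"I felt sad" as the threshold-sensitive item. `flag_overendorsed()`
returns items whose endorsement rate strictly exceeds 15% of sessions,
the expert-review trigger.

## The simulator and what passing tests show

Two generator layers serve different purposes.

*Session generator* (`simulate_session`): each module has a latent
severity $\theta \in [0,1]$; Likert levels come from fixed cut-points
(0.2/0.4/0.6/0.8) applied to $\theta$ with multiplicative log-normal
noise (sd 0.25 on the log scale), reverse items mirrored, binary items
Bernoulli($\theta$), counts Binomial(timeframe, $\theta/2$). $\theta=0$
answers symptom-absent with certainty, which makes floor behavior
exactly testable. Nonclinical/clinical populations differ only in the
$\theta$ prior (Beta(1,4) vs Beta(2,2)) — a declared convenience.

*Reliability-targeted study generator* (`simulate_study`): module
summary scores are generated directly as correlated continuous pairs
$y_{ij} = b_i + e_{ij}$, $b \sim N(0,\rho)$, $e \sim N(0,1-\rho)$ — so
the population absolute-agreement ICC equals the target $\rho$ exactly —
then decomposed into item levels summing to the rounded, clamped score.
The agoraphobia score uses a log-normal shape so its raw distribution is
right-skewed. Binary screeners draw from the exchangeable 2×2 joint with
the target κ and prevalence, for which the closed form
$p_{11} = p^2 + \kappa p(1-p)$ is exact. Rounding and range-clamping
attenuate realized Likert-score ICCs a few percent below their targets,
which is why the study-level test asserts *band-level majority
agreement* across replicates rather than coefficient equality; the
closed-form generators, which are exact, carry the parameter-recovery
tests (mean estimates within ±.05 of the generating values at n = 42
over 500 replicates).

What the simulator does **not** emulate: real item-level response
styles, acquiescence, within-module item correlations beyond the shared
score, occasion effects (available but off by default via
`occasion_shift`), or clinical-population response distributions.
Passing tests therefore demonstrate that the engine, rules and
estimators are correct and internally consistent under known ground
truth — not that the authored fixture items would achieve the published
coefficients with human respondents.

## Problem sizes and numerical choices

Diagnosis rules are kept brute-force enumerable (n ≤ 12 criteria;
the depression enumeration over all $2^9$ endorsement vectors is an
exhaustive test oracle). Default analysis sizes mirror the published
study (n = 42 paired respondents); recovery and coverage simulations
use 200–500 replicates, and bootstrap defaults to B = 2000 with smaller
B in unit tests. Ties and boundaries are all closed on the symptom side:
screen-in at the stated level ("at least sometimes" includes sometimes),
endorsement at often, banding with .60 included in good and the high
cut included in excellent, over-endorsement strictly above 15%.
Prevalence targets for the binary screeners are unpublished; the
defaults (panic .30, cannabis .20, trauma exposure .06–.50,
other-substance 1/42) are chosen once to be plausible for a young
nonclinical sample and to reproduce the two published degeneracies (the
single stable other-substance endorser; a work-trauma base rate low
enough for the bootstrap to fail).

## Known limitations

The fixture's item texts and most thresholds are authored assumptions
documented above, not the validated instrument. The rule algebra cannot
express conjunctions of required criteria or exclusion logic. Episode
history is not collected, so bipolar-course diagnoses are out of the
catalog. Severity is reported as raw Likert frequencies without normed
scores. The kappa p-values use large-sample standard errors, which are
rough below n ≈ 20.
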