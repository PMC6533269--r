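---
title: "Summed-state reconstruction and model comparison: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summed-state reconstruction and model comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(summedstates)
```

## The scientific question

How does the brain represent specific people? The summed-state hypothesis
holds that a person is represented as the profile of mental states they are
perceived to habitually experience: the multivoxel activity pattern evoked
by thinking about a target person should be reconstructible as the
frequency-weighted sum of the patterns evoked by individual mental states.
The competing trait account represents people as coordinates on a few
enduring dispositional dimensions (a low-dimensional synthesis of classic
trait scales).

`summedstates` implements both the direct test of the summed-state
hypothesis (pattern reconstruction, scored by the matched/unmatched
correlation contrast) and the comparative test (which account better
explains interpersonal similarity measured five ways: neural patterns,
pairwise similarity judgments, biographical text, binary choices, and
reaction times), together with a fully seeded synthetic-data generator so
that every stage can be validated against known ground truth.

## The direct test

Let $S \in \mathbb{R}^{V \times K}$ be the group-average mental-state
patterns over $V$ voxels and $K$ states (each participant's state patterns
are z-scored across voxels per state, then averaged across participants),
and let $R \in \mathbb{R}^{T \times K}$ be the averaged ratings of how
often each of $T$ targets experiences each state. The ratings are
*dual-normalized*: each state column is divided by its column sum, then
each target row of the result is divided by its row sum, yielding weights
$W$ whose rows are convex combinations. The reconstruction of target $t$ is

$$\hat{p}_t = \sum_{k=1}^{K} W_{tk}\, s_k .$$

Within each person-study participant, every reconstruction is Pearson-
correlated with every actual target pattern. For target $t$ the *matched*
correlation pairs $\hat p_t$ with the actual $p_t$; the $T-1$ *unmatched*
correlations pair it with other targets and are averaged (raw $r$; a
Fisher-scale option exists because the publication-style description does
not pin this down) and subtracted. Subtracting the unmatched baseline
removes any generic person-pattern shared by all targets, so whatever
remains is target-specific accuracy. Participant-mean differences enter a
two-sided one-sample t-test; Cohen's d is their mean/sd.

## The comparative test

All five similarity measures are expressed as *condensed similarity
vectors*: the strict lower triangle of the symmetric $T \times T$
similarity matrix in a fixed pair order (pairs $(i,j)$, $i<j$, ordered by
$i$ then $j$ — the same convention as `stats::dist`). The summed-state
prediction is the row-wise Pearson correlation of the raw averaged rating
matrix; the trait prediction is the negated Euclidean distance in a
3-component PCA space of the standardized trait scales (components
sign-fixed so the largest-magnitude loading is positive).

For each measure the package reports, mirroring the usual comparison-table
layout: the zero-order item-level correlation of each account with the
measure; each account's semi-partial correlation (the account residualized
on its competitor — the dependent measure is left intact, so the
coefficient is the account's *unique* explanatory power); a dependent-
correlation difference test (Steiger's 1980 $\bar Z_2^*$, evaluated at the
back-transformed mean of the two Fisher z values); and the Gaussian OLS BIC
$n\ln(\mathrm{RSS}/n) + k\ln n$ with $k$ counting predictors plus
intercept (additive constants are dropped consistently, so only
differences between models of the same measure are meaningful).

Neural similarity additionally gets a group-level treatment: each
participant's condensed neural similarity is correlated with each
prediction, coefficients are Fisher-transformed and entered into one-sample
t-tests, with Cohen's d on the z scale. The share of *reliable* neural
variance explained by the summed states is estimated by disattenuation:
the squared item-level correlation divided by the measure's split-half
reliability (random half-splits of participants, Spearman–Brown corrected,
averaged over splits). Shares slightly above 1 can occur by sampling error
and are flagged with a warning rather than truncated.

Choices and reaction times from the triadic similarity task are modeled
with fixed-effects regressions — a logistic model of choosing option A and
a linear model of log RT — on standardized similarity-difference
predictors, with a participant-cluster bootstrap (resampling participants
with replacement, refitting, percentile 95% interval of the coefficient
difference) standing in for mixed-effects contrasts. Dropping the random
effects is justified by the resampling itself: clustering the bootstrap by
participant captures the participant-level dependence the random effects
would have modeled. The fit-free complement is the unfitted choice
accuracy: the fraction of trials on which the chosen option has strictly
higher model similarity to the reference (exactly tied trials are excluded
from both numerator and denominator — a tied trial is uninformative about
either account).

## The synthetic-data generator

`generator_config()` fixes the study conditions; its defaults mirror the
design this package emulates: 60 targets, 15 states, 29 person-study and
28 state-study imaging participants, 644 online raters, 103 behavioral
participants with 50 triadic trials each, and 13 trait scales. The voxel
count defaults to 500: pattern correlations are stable at that length and
nothing downstream depends on the absolute voxel count. Noise magnitudes
(participant noise sd 1 in units of the unit-variance true patterns, rater
noise sd 0.05 against mean weights of $1/K$, trait noise sd 0.5) are
conventional choices — the underlying rater-disagreement magnitudes are not
published — selected once to produce intermediate, realistic effect sizes.
With the defaults the generated data land close to the qualitative
published picture (e.g., unfitted choice accuracy near 67% with the default
logistic slope of 2.5 on similarity differences).

The generative skeleton:

* **State patterns** are independent standard-normal voxel values,
  column-standardized at generation so each true pattern has exactly mean
  0 and unit sd. Because the analysis z-scores patterns anyway, this costs
  no generality and makes the noise-free analysis path an exact identity.
* **Frequency weights** are symmetric-Dirichlet rows (concentration 1:
  uniform on the simplex) that are then Sinkhorn-balanced to row sums 1
  and equal column sums. A matrix with equal column sums is a fixed point
  of the dual normalization, so noise-free ratings reproduce the
  generating weights exactly and noise-free reconstructions are exact.
  Without the balancing step the dual normalization would distort the
  truth and the noise-free matched correlations would not be 1 — an
  identifiability choice, not a statistical one.
* **Person patterns** are $S w_t$ plus optional residual signal
  (`residual_signal_sd`) — person-specific structure the states cannot
  explain — and each imaging participant observes truth plus homoscedastic
  i.i.d. voxel noise. Spatial and temporal noise correlations of real fMRI
  are deliberately out of scope: the generator validates the statistical
  machinery, not scanner physics.
* **Traits** are noisy linear functions of the log weights
  (`log(pmax(w, 1e-6))`; the floor avoids $-\infty$ while preserving
  order). `trait_noise_sd` is the knob that controls how much independent
  information traits carry: at 0, traits are fully state-determined and
  the trait account should be fully mediated downstream.
* **Text** builds each target's word-probability vector as a noisy linear
  map of its weight row through a shared states-by-vocabulary topic
  matrix, renormalized, then draws multinomial token counts.
* **Choices** follow a logistic model on the true state-similarity
  difference; log RTs are normal around `log(rt_base_ms)` with a negative
  slope on the *absolute* standardized similarity difference (easier
  discriminations are faster), then exponentiated.
* **Similarity judgments** are the true state similarity plus a shared
  systematic distortion plus averaged rater noise.

One top-level seed fans out to named substreams per stage, so changing
options for one stage never shifts another stage's draws, and a fixed
configuration is bit-reproducible end to end.

## Numerical and design choices

* **Z-scoring axis.** Patterns are standardized per condition across
  voxels (the standard MVPA reading): it removes per-condition amplitude
  so correlations reflect pattern shape. Sample (n−1) sd everywhere.
* **Voxel selection.** Split-half voxelwise reliability (a voxel's
  condition-profile correlation between half-averages, averaged over
  seeded splits) is thresholded on a grid; the returned mask maximizes
  patternwise reliability, with ties resolved toward the lowest threshold
  (retain more voxels). The default grid starts at −1, a no-op threshold,
  so the selected mask can never be worse than the full voxel set. The
  original selection jointly optimized voxelwise and patternwise
  reliability; the grid-argmax here is a declared simplification.
* **Semi-partial df.** The t test on the semi-partial coefficient uses
  $n-3$ degrees of freedom, accounting for the control variable.
* **Degenerate inputs are errors, not silent repairs**: constant pattern
  columns, zero rating rows/columns, collinear predictors, exact-fit BIC,
  and |r| = 1 entering a Fisher transform all raise descriptive errors.
  Two deliberate exceptions: non-positive split-half reliability is
  floored at a small positive value with a warning (a reliability of
  exactly 0 would make disattenuation undefined), and identical
  predictors in the dependent-correlation test return $Z = 0$, $p = 1$.
* **Text frequencies** are within-document relative frequencies before
  absolute differences are summed; raw counts would conflate document
  length with content.

## What the synthetic validation does and does not show

The test suite validates the machinery under the generator's assumptions:
exact recovery in noise-free limits, calibrated error rates under nulls,
monotone degradation with noise, and parameter recovery within sampling
error. Three findings from that validation are worth understanding before
interpreting pipeline output on real data:

* **Stimulus-as-fixed-effect.** The participant-level t-test on
  reconstruction differences is calibrated when actual patterns are
  independent across participants. When all participants share the same
  true person patterns and the reconstruction weights are misaligned
  (e.g., row-permuted), the misalignment induces a matched-minus-unmatched
  shift that is *common to all participants*; the t-test treats it as
  signal and rejects far above its nominal rate. This is the classic
  fixed-stimuli caveat of within-sample designs, and it is why the null
  calibration check draws actual patterns independently per participant.
* **Linear controls do not remove nonlinear shared signal.** With
  trait noise at 0, traits carry no information beyond state frequencies,
  yet on the *text* measure the trait semi-partial does not vanish: text
  similarity is a nonlinear function of the frequency profiles, and
  residualizing on the (linear) state-similarity vector leaves shared
  nonlinear structure behind. On the similarity-judgment measure — whose
  generated signal is linear in state similarity — full mediation holds
  almost exactly. Semi-partial "unique variance" claims are therefore
  specific to the linear feature set used as control.
* **Heterogeneous attenuation.** Targets differ in true pattern variance,
  so participant noise shrinks each pair's expected measured correlation
  by a pair-specific factor $a_t a_u$, $a_t = s_t/\sqrt{s_t^2+\sigma^2}$.
  That stable distortion counts as reliable variance, so the
  disattenuated share of a predictor that ignores it plateaus below 1
  (about 0.8 under the defaults). The consistency check therefore uses
  the expected measured similarity $\rho_{tu} a_t a_u$ as the predictor,
  and the share then converges to 1. On real data, reliable-variance
  shares inherit the same caveat.

Also note that under the default generator the reaction-time rows of the
comparison table are near-null by construction: generated RTs depend on
the *absolute* similarity difference (difficulty), while the analysis
predictor is the signed difference, whose linear RT effect is symmetric
around zero. The RT machinery is validated separately by direct slope
recovery on signed predictors.

Problem sizes used in the validation suite (chosen to make the relevant
sampling distributions well-resolved): 1,000 simulated datasets at
$T=20$, $K=10$, $V=200$, 15 participants for the null calibration; 2,000
Monte-Carlo datasets of 105 pairs for the dependent-correlation
calibration; 20 seeds at 100 participants for disattenuation consistency;
5 replicate datasets of 5,000 trials for behavioral slope recovery.

## A worked run

```{r example, eval = FALSE}
cfg <- generator_config(seed = 1)
report <- run_pipeline(cfg)
print(report)
```

`run_pipeline()` generates the dataset, executes every stage, and returns
a `run_report` whose comparison table has one row per measure and account.
`write_dataset()` + `run_pipeline_files()` round-trip the same analysis
through CSV files; `scripts/acceptance.R` wraps the default run and writes
the headline quantities as JSON.

## Known limitations

* The generator's noise is white across voxels and raters; real fMRI and
  rating data have structured noise, so real-data effect sizes will not
  match synthetic ones.
* Mixed-effects models (random slopes, Satterthwaite df) are replaced by
  the participant-cluster bootstrap throughout.
* The published voxel mask, trait loadings, and headline effect sizes are
  properties of the original datasets and are not reproduced here; the
  pipeline reproduces the *procedures*.
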