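---
title: "Protease profiling of biopsy supernatants: models and methods"
author: "ProteasePanel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protease profiling of biopsy supernatants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteasePanel)
```

## The scientific setting

Colonic mucosal biopsies incubated in buffer release soluble mediators into
the supernatant. Supernatants from irritable bowel syndrome (IBS) patients
and from ulcerative colitis (UC) patients in remission activate enteric
neurons, while supernatants from healthy controls (HC) barely do; proteases
are the dominant neuroactive component, and in IBS they act through
protease-activated receptor 1 (PAR1). This package implements the
computational side of that analysis as a reusable, tested workflow:

1. variance-stabilizing normalization of a label-free protein intensity
   matrix (proteins x samples, three sample groups),
2. per-protein moderated differential-abundance statistics with false
   discovery control and an abundance-pattern classification,
3. exhaustive 2-5 protein biomarker-panel search scored by linear
   discriminant analysis (LDA) under repeated stratified train/test splits,
   with ROC/AUC summaries, and
4. the neuroindex statistics for ganglion imaging recordings, with the
   accompanying nonparametric test battery and the protease-abundance
   versus antagonist-inhibition correlation.

A synthetic-data generator emulates the joint structure of both data types
and carries ground-truth labels, so every stage can be exercised in
recovery experiments.

## Variance-stabilizing normalization

Label-free intensities follow an additive-multiplicative error model: for
protein $k$ in sample $s$,

$$x_{ks} = e^{\eta_{ks}}\,\mu_{ks} + \varepsilon_{ks},$$

with lognormal multiplicative noise $\eta$ and additive noise
$\varepsilon$. The standard deviation of $x$ therefore grows with its
mean. The generalized-log transform

$$h_s(x) = \operatorname{arsinh}\!\left(\frac{x - a_s}{b_s}\right)$$

removes this dependence: it is linear where additive noise dominates and
logarithmic where multiplicative noise dominates, and
$h(x_1) - h(x_2) \to \ln x_1 - \ln x_2$ for large intensities.

`vsnNormalize()` estimates the per-sample calibration $(a_s, b_s)$ by
profile maximum likelihood: per-protein means and the common error
variance are profiled out analytically, leaving a smooth objective in the
$2S$ calibration parameters that is minimized by L-BFGS with analytic
gradients. Robustness is least-trimmed-squares style: after each fit the
10% of proteins with the largest residual sum of squares are set aside
and the fit repeated until the calibration is stable (at most 50 rounds).

Numerical notes, all visible in `vsnCalibration()` diagnostics:

* The offsets $a_s$ lie on a nearly flat likelihood ridge (they matter
  only relative to $b_s$), so convergence is declared on the
  $(a_s/b_s,\ \log b_s)$ scale at tolerance $10^{-8}$, with the relative
  objective change as a secondary stop against optimizer jitter, and the
  trim set additionally required to be stable.
* Scales are parameterized as $\log b_s$, keeping $b_s > 0$ by
  construction; a degenerate (constant) sample column is an error, as is
  any missing intensity.
* Scaling an entire sample by a factor $c$ is absorbed into $b_s$ - the
  transformed values are invariant up to fit tolerance. This holds on
  data that match the error model; on data with essentially no additive
  noise floor the likelihood in $b_s$ flattens (any small $b_s$ yields
  the plain logarithm) and only the transformed values, not the
  individual parameters, are stable.

Downstream statistics use $h/\ln 10$ (`glogValues(x, base = 10)`), so
group differences read directly as log10 abundance ratios in the
high-intensity regime, the unit used throughout the reported protease
tables.

## Moderated differential abundance

For each protein, `fitGroupModel()` fits the one-way layout across the
three groups by least squares: group means, residual variance $s_g^2$ and
residual degrees of freedom $d_g = n - 3$. With 22 samples a raw
per-protein variance is unstable, so `ebayesModerate()` shrinks it with
the standard empirical-Bayes hierarchy: assuming
$s_g^2 \mid \sigma_g^2 \sim \sigma_g^2\chi^2_{d_g}/d_g$ and a scaled
inverse chi-squared prior $\sigma_g^2 \sim s_0^2 d_0/\chi^2_{d_0}$, the
hyperparameters $(d_0, s_0^2)$ are estimated by matching the observed
mean and variance of $\log s_g^2$ to the marginal scaled-F distribution
(trigamma inversion by damped Newton, tolerance $10^{-8}$), and each
variance becomes

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

always bracketed between $s_g^2$ and $s_0^2$. When the spread of
$\log s_g^2$ is no larger than chi-squared sampling alone explains,
$d_0 = \infty$ (capped at $10^6$ in downstream arithmetic) and all
moderated variances collapse to the common value.

Pairwise contrasts (IBS vs HC, UC vs HC, IBS vs UC; positive = higher in
the first-named group) are tested with moderated t statistics on
$d_g + d_0$ degrees of freedom, and the overall three-group effect with
the moderated F on $(2,\ d_g + d_0)$ degrees of freedom; with $d_0 = 0$
both reduce exactly to the classical ANOVA statistics, which is used as
an oracle check in the tests. Benjamini-Hochberg adjustment is applied to
the overall F p-values and drives `selectDifferential()`; the pairwise
p-values are reported unadjusted, mirroring the layout of the published
protease table. This F-based reading of the "differential between the
three groups" selection is the package default; the pairwise-union
alternative can be composed from the same table if wanted.

`classifyPattern()` maps each protein's three (sign, significance) pairs
at $\alpha = 0.05$ onto the eight abundance-pattern classes used for the
protease table (up in IBS vs both; up in IBS vs HC with UC also up vs HC;
up in IBS vs HC only; up in IBS vs UC only; and the mirrored down
classes; else "other"). Applied to the 17 printed reference rows bundled
in `referenceProteaseTable()` it reproduces the printed 4/1/3/2/4/2/1
partition exactly; the two complement C3 entries share one UniProt id and
are disambiguated with a `.b` suffix, a packaging convention.

## Panel discovery

The candidate set is the protease-flagged proteins significantly more
abundant in IBS than HC. `enumerateSubsets()` lists every panel of 2-5
candidates; each panel is scored by `repeatedSplitAccuracy()`: 100
stratified random splits into 2/3 training and 1/3 test samples, an LDA
fit on the training part, and the proportion of correct test predictions,
summarized by the replicate mean. The train fraction is a convention
choice (the split procedure itself, and the 100 replicates, follow the
study design); it is configurable. Each panel draws its splits from its
own seed substream derived from the master seed, so leaderboard entries
do not depend on evaluation order.

The LDA (`ldaFit()`) uses class means and the pooled within-class
covariance with equal class priors (the compared cohorts are nearly
balanced) and an always-on ridge $\lambda = 10^{-6}\,\mathrm{tr}(S)/p$
for small-sample stability; exact score ties go to the first class in
label order. `rankPanels()` sorts by mean accuracy, breaking ties in
favour of smaller panels, then lexicographically.

ROC curves (`rocAuc()`) sweep the threshold over the unique scores and
integrate by the trapezoid rule; this equals the Mann-Whitney
pair-counting statistic with half-weighted ties, implemented
independently in `pairCountAuc()` and asserted equal to $10^{-12}$ in the
tests. Panel ROC uses the full-data discriminant score
(`panelScore()`), which is invariant in AUC terms under any strictly
increasing transform; whether a cross-validated score should be used
instead is a design choice - the full-data score is the default because
the accuracy, not the ROC, carries the validation burden.

## Neurophysiology statistics

The per-ganglion neuroindex is

$$\text{neuroindex} = 100\cdot\frac{\text{responders}}{\text{neurons}}
  \cdot \overline{f}_{\text{responders}},$$

with $\overline f$ the mean spike frequency (Hz) of the responding
neurons; it is zero exactly when no neuron responds, and consistent under
splitting a ganglion's responders into sub-records (weighted-mean
identity). The calcium-imaging analogue multiplies the mean peak
$\Delta F/F$ of responders by the percentage of responders relative to
the nicotine-responsive cells. Responder calls are made upstream by the
imaging software; recordings arrive with counts and per-responder
magnitudes.

Between-group comparisons aggregate to one value per patient first
(median across that patient's ganglia; configurable to the mean) and use
Kruskal-Wallis with Dunn's all-pairwise post-hoc z statistics and
Bonferroni adjustment ($p_{\text{adj}} = \min(1, 3p)$ for three groups).
Paired designs (antagonist, inhibitor) use the Wilcoxon signed-rank test
- exact for up to 25 tie-free non-zero differences, continuity-corrected
normal approximation otherwise, zero differences dropped; an all-zero
comparison is flagged degenerate rather than tested. Unpaired two-group
comparisons use the Mann-Whitney rank-sum test. The link between
proteome and physiology is the Pearson correlation between per-patient
protease abundance and the antagonist-induced percent decrease of the
neuroindex, $100(\text{pre}-\text{post})/\text{pre}$, computed per
patient and reported with $n$ alongside $r$ and $p$ (the reference
tables do not state their $n$).

## What the generator emulates - and what it does not

`synthProteomeConfig()` defaults encode the study conditions: 1081
proteins, 22 samples split 7 HC / 8 IBS / 7 UC (the split is not stated
in the reference study and is configurable), 204 differential proteins
with planted |log10| effects uniform on 0.1-1.6 distributed over the
seven pattern classes in the reference proportions, 17 protease-flagged
proteins inside the differential set, multiplicative noise with CV 0.36
(a log10 sd of about 0.15, a realistic between-patient spread for
secreted proteins), additive noise sd 500 against baselines of
$10^{5\pm0.8}$, and no missing values (an intensity-dependent dropout
switch exists but is off, matching the complete reference matrix).
Planted patterns use intermediate UC levels where a single-contrast
pattern would otherwise drift into a two-contrast class.

`synthNeuroConfig()` defaults match the printed cohort (7 HC, 14 IBS, 12
UC patients), responder probabilities 0.25/0.81/0.80 and mean responder
spike frequencies 1.5/3.8/3.3 Hz with lognormal per-neuron variation;
ganglion sizes are uniform on 3-15 neurons (unstated in the study;
plausible submucous ganglia). Per-neuron frequencies are drawn so the
per-ganglion mean equals the configured group mean, which makes the
group median neuroindex converge to $100\,p\,f$.
`simulatePairedInhibition()` plants an exact population correlation
between abundance and percent inhibition (default $-0.69$, the scale of
the strongest printed correlation); post values can exceed pre only
through Gaussian noise in the planted decrease, with probability about
$7\times10^{-6}$ at the defaults.

What passing recovery tests on these data do **not** show: the generator
plants independent Gaussian log-abundances - real supernatant proteomes
have correlated proteins, batch structure, heavier tails and occasional
missingness, and real responder counts are not binomial. Recovery rates
measured here are therefore upper bounds on what the same pipeline
achieves on real data, and the neurophysiology medians of the study
itself (which depend on unreleased per-patient recordings) are emulated
only in their qualitative ordering (IBS close to UC, both far above HC).

## The panel-recovery benchmark

`panelBenchmarkConfig()` fixes the condition for the panel recovery
experiment: eight protease candidates of which three are informative with
equal planted log10 effects of 0.30 - the scale at which a single marker
classifies imperfectly (AUC in the high 0.80s, matching the printed
single-protease AUCs) while the triple reaches the study-scale accuracy
near 0.96-0.98 - and 80 patients per compared group. The group size is an
identifiability choice, not a cohort emulation: at the study's 7-8
samples per group the search reproduces the high top accuracy, but test
splits of five samples are saturated by any two informative markers, so
the identity of the full planted triple is not recoverable from the
leaderboard (the classic feature-peaking regime). This is a real and
instructive limitation of exhaustive panel search at biopsy-study sample
sizes; the package asserts the accuracy property at 7+8 and the recovery
property at the benchmark size.

## Problem sizes and numerical defaults

The test suite and the acceptance script run entirely on synthetic data
at the sizes above: ten full pipeline replicates for differential
recovery, twenty for panel recovery, 1000 replicates per test for type-I
calibration, 5000 variances for hyperparameter recovery, 200 datasets for
the chance-AUC simulation. Tolerances asserted in tests are stated next
to each check: exact identities at $10^{-10}$-$10^{-12}$, Monte-Carlo
recoveries at 5-15% relative, binomial bands at roughly 3.5 standard
errors.

## Known limitations

* The calibration fit assumes complete positive intensity matrices;
  missing values must be handled (filtered or imputed) upstream.
* The pattern classification is a decision rule on marginal tests, not a
  joint model; proteins with contradictory significant contrasts fall
  into "other".
* LDA assumes a shared within-class covariance; markers with
  group-specific variance structure would favour quadratic rules that
  are out of scope here.
* Dunn's z uses the normal approximation; for very small per-group
  counts its familywise control is conservative rather than exact.
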