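---
title: "Measuring the gap between disease burden and trial evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the gap between disease burden and trial evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialgap)
```

## The question

Randomised controlled trials (RCTs) are the costliest and most informative
unit of clinical evidence, and there is no guarantee that they are spent
where disease burden is greatest. A bibliometric way to ask the question is
to count published RCT reports per broad disease area — the 22 level-2
cause categories of the Global Burden of Disease (GBD) study — and regress
those counts on the burden each category imposes, measured in
disability-adjusted life years (DALYs). Categories falling far below the
regression line are under-researched relative to their burden; the
socioeconomic distribution of that burden can then be added as a covariate
to ask *whose* burden attracts research.

Real inputs for such a study are a classifier-annotated bibliographic
database and the GBD estimates. Both are large, external, and slowly
changing, which makes the analysis hard to test. This package therefore
ships the entire analysis together with a synthetic-corpus generator whose
ground truth is known exactly, so every stage — mapping, counting,
misclassification adjustment, regression — can be validated end to end
without any download.

## The model

For category \(i\) and year \(t\), with article count \(N_{it}\) and global
DALYs \(D_{it}\), the primary specification is

\[
\log N_{it} = \beta \log D_{it} + \alpha_t + \epsilon_{it},
\qquad \epsilon_{it} \sim N(0, \sigma^2),
\]

with the year entering as a categorical term, either as fixed effects or as
random intercepts (`burden_fit(..., effects =)`); `hausman_test()` compares
the two estimators over the burden coefficients. Because publication takes
time, the distributed-lag variant replaces the single elasticity with
\(\sum_{j=0}^{L} \beta_j \log D_{i,t-j}\) and reports the cumulative
elasticity \(\sum_j \beta_j\) with a delta-method interval. The location
variant adds \(\beta_{loc} \log R_{it}\), where \(R_{it}\) is the ratio of
DALYs occurring in high-SDI (top fifth of countries by Sociodemographic
Index) to low/middle-SDI countries: it enters in logs so that a
proportional shift of burden towards richer countries has a constant
percentage effect on publications.

A coefficient \(\beta\) in any of these log-log models converts to a
percentage statement through

\[
\Delta\% = 100\left((1 + p/100)^{\beta} - 1\right),
\]

implemented in `elasticity()`. For example a coefficient of 0.52 implies a
5% rise in annual RCT output per 10% rise in DALYs.

## What the generator emulates

`ground_truth()` fixes the world; `simulate_corpus()` realises it. The
stated world is:

* **Publication law.** Log expected article counts follow the model above.
  Year effects default to a linear ramp from 1.2 to 3.0 over the panel,
  reproducing roughly six-fold growth in annual RCT output over 1990–2017
  and a corpus in the few-hundred-thousand range at full scale. Counts are
  Poisson draws around the exponentiated (noisy) linear predictor, giving
  integer counts with realistic dispersion.
* **Noise.** `noise_sd` is a free parameter; its default 1.7 was set by
  measuring the adjusted R² of the primary fit at paper scale across noise
  levels and choosing the value that lands near the published 0.13. That
  much unexplained variance is a statement about the world — research
  effort tracks burden only weakly — and it is why single-panel estimates
  of \(\beta\) carry wide intervals.
* **Burden.** Per-category DALYs (in thousands) are lognormal,
  `meanlog = log(2800)`, `sdlog = 0.6`, matching the scale and spread of
  published category-level burden tables, with small linear trends and a
  mild random walk. The random walk matters: it provides the
  within-category variation across lags that makes distributed-lag
  coefficients identifiable. DALYs split exactly into YLD + YLL and into
  high-SDI versus low/middle-SDI parts via a per-category share.
* **Trial sample sizes.** Lognormal with `meanlog = log(72)` and `sdlog =
  (log 195 − log 32)/(2 × 0.6745)`: the median matches 72 exactly and the
  IQR approximately (a lognormal cannot match an asymmetric-in-logs IQR
  exactly; the implied quartiles are ≈ 29–178). 34% of articles carry no
  extracted size; extracted sizes are wrong with probability 0.15, with a
  rounded Gaussian error (sd 8 participants) clamped at 1.
* **Duplicate publication.** Trials publish `articles_per_trial` articles
  on average (default 1.3, the published mean; per-category values may be
  supplied to emulate the published 1.2–1.5 range); half of trials carry a
  visible registry identifier.
* **Classifier error.** Gold labels are corrupted to predictions at stated
  per-task precision and recall (default 0.95/0.95): misses are dropped at
  rate \(1 - r\), and false positives are injected at the Poisson rate that
  makes corpus-level precision converge to \(p\). The RCT and human checks
  are treated as one combined task, since the published validation labelled
  "RCT in humans vs not" as a single judgement.
* **Geography.** First-author countries are drawn with probability 0.82
  from top-quintile SDI countries, the published share.

### What the generator does not emulate

No text is generated — terms are identifiers, not abstracts — so nothing
here tests the upstream NLP. The MeSH hierarchy is flat (each term maps to
one category); mapping-curation errors are out of scope. Cross-category
outcome terms (`outcome_prob`, default 0.25) create prevention-trial
relevance, which means per-category counts exceed the per-condition
publication law by design; the end-to-end recovery oracle therefore runs
with `outcome_prob = 0`, and a green end-to-end test establishes correct
plumbing, not that treatment/prevention duality is ignorable. A green
calibration test establishes that the generator hits its own targets, never
that the published PubMed-scale values are reproduced — they derive from
the real corpus and are used here only as calibration targets and
structural templates.

## Misclassification-adjusted counts

Automated counts inherit classifier error. With validation precision
\(p\) and recall \(r\), the adjusted count is \(\hat{N} = N_{raw} \, p /
r\): of the predicted positives, a fraction \(p\) are genuine, and the
genuine ones are a fraction \(r\) of all true positives. Uncertainty is
propagated by bootstrap: `bootstrap_pr()` resamples the validation rows
(unstratified, per task, exactly as the sample was drawn) and
`prediction_interval()` reports the 2.5th/97.5th percentiles of the
adjusted counts across draws. `chain_adjustment()` composes tasks
multiplicatively, pairing draws by index.

Numerical choices, stated once:

* **Zero cells.** A bootstrap resample with no true positive gets 0.5
  added to every confusion cell *for that draw only* — small validation
  samples (250 articles across 22 categories) make empty cells a real
  possibility, and discarding such draws would bias the interval.
* **Point estimate.** The default point is the plug-in adjustment at the
  full-sample operating point, with the draw median available via
  `point = "median"`; published headline counts with asymmetric intervals
  are consistent with the plug-in convention, but the choice is not stated
  in routine reports, so both are provided. Only the median point is
  guaranteed to lie inside its interval.
* **Percentiles.** Empirical quantiles with linear interpolation
  (`quantile` type 7) everywhere — intervals, participant summaries,
  everything — so IQRs are reproducible across implementations.
* **Category operating points.** The category task's validation sample is
  pooled across categories; 250 rows cannot support 22 per-category
  operating points.
* **Sample-size uncertainty** uses the empirical multiset of signed
  extraction errors from validation pairs, resampled with replacement onto
  every extracted size (clamped at 1), with percentile intervals for the
  median, quartiles and total (`simulate_size_summaries()`).

## Regression choices

* **Zero counts** enter as \(\log 0.5\) and are flagged; with the default
  world this touches well under 1% of rows.
* **Estimation sample for lag comparisons.** All candidate lag orders are
  fitted on years \(\ge\) start + \(L_{max}\) (`common_lags`), because
  information criteria across different samples are meaningless;
  `compare_models()` refuses fits whose samples differ.
* **Information criteria** use the full Gaussian log-likelihood
  (`stats::logLik` convention; random-effects fits use maximum likelihood,
  not REML), so differences between models are meaningful, levels are not.
* **Intervals** are normal-theory Wald intervals without small-sample
  correction, matching routine reporting at panel sizes in the hundreds.
* **Back-transforming predictions.** Expected counts default to naive
  exponentiation of the fitted log mean; Duan's smearing factor is a flag
  (`expected_vs_observed(..., smearing = TRUE)`). With the published
  table's construction unstated, both are reported rather than reconciled.
* **Expected-versus-observed tables** aggregate signed differences into
  4-year bins plus a total; bins sum to the total exactly before rounding.
  Which fitted model feeds the table is the caller's choice; the primary
  model is the default, as in the published table.
* **Duplicate-publication sensitivity.** Mean articles-per-trial is
  estimated per category from registry-identifier groups and counts are
  divided by it. Under uniform duplication \(d\) this provably shifts only
  the intercept (by \(-\log d\)), which the tests verify in closed form;
  category-varying duplication moves \(\beta\) by a computable amount.
* **Counts fed to the regressions are raw** (misclassification-unadjusted)
  article counts; nothing in the published analysis indicates the adjusted
  counts enter the models. Adjusted-count regression is possible by
  passing an adjusted panel explicitly.

## Determinism and exactness

Every stochastic stage derives its seed from the master seed by stage name,
so stages are reproducible in isolation and `run_pipeline()` reruns are
checksum-identical. One generator subtlety: with `noise_sd = 0` the DALY
series is *snapped* so that \(\exp(\alpha_t + \beta \log D_{it})\) is an
exact positive integer for every cell. Without snapping, rounding expected
counts to integers would break the log-linear law by up to half a count and
noise-free recovery would only be approximate; with it, article counts are
genuinely discrete *and* the law holds exactly, so the recovery oracle can
demand agreement to 1e-8. When \(\beta = 0\) (or a zero contemporaneous lag
weight) snapping is impossible and counts are simply rounded.

With lag weights, the first \(L\) years of the predictor clamp missing lags
to the series start; fits on the common sample never touch those rows, and
the convention is documented rather than hidden.

## Known limitations

* The estimand of the log-scale OLS differs slightly from the generator's
  Poisson mean at very small expected counts (the floor and Jensen effects
  at near-zero cells); at the default world this is negligible, as the
  recovery tests show, but a world tuned to many near-empty cells would
  expose it.
* Random-effects adjusted R² is computed from conditional fitted values
  with \(k\) equal to the number of fixed coefficients — a pragmatic
  analogue, not a settled definition.
* The Hausman statistic uses a pseudo-inverse of the variance difference,
  which is not guaranteed positive definite in finite samples; the degrees
  of freedom equal its numerical rank.
* Articles relevant to zero categories are retained in global totals but
  absent from per-category tables, so category tables are conditional on
  mappability, as in published category tables.
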