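---
title: "Discovering and validating prognostic transcript panels with paucpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating prognostic transcript panels with paucpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paucpanel)
```

## The design this package implements

`paucpanel` operationalizes a two-cohort prognostic-biomarker workflow for
clinically localized prostate cancer: a population-based *discovery* cohort
(278 patients with no recurrence over long follow-up vs. 27 who progressed
to metastasis or death from the disease) is used to find transcripts whose
tumor expression adds prognostic value beyond Gleason score, and an
independent *validation* cohort (46 vs. 32, a nested case–control design)
is used to confirm them. The same workflow applies to any case–control
expression study with a dominant clinical covariate; prostate-cancer
vocabulary is used throughout because the defaults encode that design.

Three statistical ideas carry the method:

* **Partial AUC at high specificity.** A prognostic classifier that flags
  patients for aggressive treatment must have a low false-positive rate, so
  transcripts are ranked not only by overall AUC but by the area under the
  ROC curve restricted to false-positive rates below 5%.
* **Improvement over the clinical standard.** Transcripts are selected by
  forward logistic model building *on top of* a Gleason-score base model,
  so a transcript that merely proxies Gleason is never selected.
* **Stability under resampling.** Forward selection on a single sample is
  notoriously unstable with 27 events; repeating it on bootstrap resamples
  and keeping only transcripts selected repeatedly converts an unstable
  search into a reproducible panel.

## Statistical conventions

**AUC.** The Mann–Whitney estimator: the proportion of (case, control)
pairs ordered correctly, tied pairs counted 1/2. Computed from midranks;
`roc_auc(s, y) + roc_auc(-s, y) = 1` holds exactly.

**pAUC.** The empirical ROC curve is the step curve with *diagonal*
segments at tied scores (the limit of jittering ties), and the pAUC is its
integral over false-positive rate $\in [0, 1 - \text{floor}]$ with linear
interpolation at the boundary. It is reported **unnormalized**: with the
default floor of 0.95 the maximum attainable value is 0.05 and the chance
value is $0.05^2/2 = 0.00125$. This convention was chosen because published
per-transcript pAUC values in this design (0.002–0.019) live on that scale.

**Permutation p-values.** Class labels are permuted `n_permutations` times
(default 10,000) and $p = (1 + \#\{T_{perm} \ge T_{obs}\})/(B+1)$; the
add-one convention means $p$ is never 0 and the smallest reportable value
is $1/(B+1)$. One-sided "greater" is the default because transcripts are
orientation-fixed in discovery before validation (all validation AUCs are
then $\ge 0.5$ under the discovery direction); a `two_sided` alternative
recentres at the chance value and compares absolute deviations.

**Bootstrap confidence intervals.** Cases and controls are resampled
separately (stratified), the statistic recomputed `n_bootstrap` times
(default 2000), and the percentile 2.5%/97.5% interval reported. The
percentile form was chosen over BCa for transparency; its coverage at the
validation sample sizes is checked empirically by the test suite.

**t-test.** Welch's unequal-variance form by default: the group sizes here
are badly unbalanced (278 vs 27), which makes the pooled form fragile; the
pooled test remains available via `equal_variance = TRUE`.

**FDR.** Benjamini–Hochberg step-up. The family size `m` may exceed the
number of p-values supplied: in the validation stage the FDR family is the
full robust panel (48) even though only a subset may be tabulated, which
treats the untabulated tests as less significant — the conservative
direction. `q >= p` always holds, and q-values are order-invariant.

## Preprocessing

The default order is probe filtering → quantile normalization → log2
transform → batch adjustment; each step is a separate function, so other
orders are possible when data arrive partially processed (simulated data,
for instance, are generated directly on the log2 scale).

*Quantile normalization* forces every sample column onto the across-sample
mean of order statistics. Ties receive the mean of the reference values at
their tied ranks (fractional midranks interpolate linearly); this makes the
operation deterministic and idempotent.

*Batch adjustment* is an explicit location-scale correction: per probe and
batch, values are centred at the batch mean, rescaled to the pooled
within-batch standard deviation, and the probe's grand mean is restored
exactly. An optional shrinkage (`shrink = TRUE`) pulls per-probe batch
means and SDs toward their across-probe averages with weight
$n_b/(n_b+1)$, damping noisy estimates in small batches. This is
deliberately *not* an empirical-Bayes procedure: the pipeline's downstream
statistics need only batch location/scale removal, and the simple form is
exactly specified and therefore exactly testable. A consequence worth
knowing: a pure location shift added to one batch is removed completely,
but the global mean of the input (which the shift moved) is preserved — the
adjusted data are shifted by a constant relative to the never-perturbed
data. Only between-batch structure is meaningful after adjustment.

*Replicate QC* computes Pearson correlations across probes for declared
blind-duplicate pairs and flags pairs below 0.95 (assay-quality duplicates
in this kind of data correlate at 0.98–0.99).

## Screening

Each transcript is oriented so its AUC is at least 0.5 (the sign is kept —
it is the discovery direction used later for concordance), then ranked by
AUC and by pAUC. Rank cutoffs are `floor(m * fraction)` with a minimum of
one; the defaults (top 4% by pAUC, top 1% by AUC) are combined by **union**.
The union reading is the arithmetically consistent one: with ~26,000
transcripts an intersection could keep at most the smaller cutoff (~260),
while the reduced panels reported for this design are ~1,200 — between the
larger cutoff and the sum of both. Rank ties break by transcript order
(deterministic); an AUC of exactly 0.5 takes orientation +1 by convention.

## Forward selection and stability

The base model is a logistic regression of outcome on Gleason score.
Gleason enters as a single **ordinal** covariate coded 1–4 over the
categories ≤6, 3+4, 4+3, 8–10 by default: with only 27 events, a
categorical coding spends three degrees of freedom where one buys nearly
the same discrimination; the categorical option exists
(`gleason_coding = "categorical"`). Age, PSA category and stage are
excluded from the base model by default, mirroring the design decision that
they do not improve on Gleason alone; they can be assessed with
`fit_logistic()` directly.

At each forward step, every remaining candidate is added singly and the
step keeps the candidate maximizing the criterion's figure of merit: model
pAUC gain, model AUC gain (both on in-sample fitted probabilities — the
reported base-model discrimination in this design is in-sample), or the
smallest Wald p of the new term. Stopping rules: pAUC gain < 0.0005, AUC
gain < 0.005, or Wald p > 0.05, with a panel cap of 10 per run guarding
against degenerate long panels on resamples.

`stability_select()` repeats this on `n_stability` bootstrap resamples
(default 1000), **stratified by outcome** — with 27 events, unstratified
resamples frequently lose or nearly lose the case class — and tallies
selections per criterion. A transcript is *robust* when it appears strictly
more than `min_count` times (default 40) under at least one criterion. When
the number of resamples is scaled down, `min_count` should be scaled
proportionally (the tests use 8/200, the same 4% rate).

### Numerical notes on the logistic fits

Fits use iteratively reweighted least squares with convergence declared at
a relative deviance change below 1e-8 (50 iterations maximum; candidate
evaluations inside the selection loop use 1e-6/30, since metric gains are
compared at the 1e-3 scale). Covariates are centred internally — the fit is
identical, but it keeps the intercept near zero so that the separation
check (any coefficient magnitude above 30 on the centred scale, or deviance
collapsing below 1e-6) is scale-honest; log2-expression covariates sit
around 7–14, where a raw-scale intercept bound would misfire. Separated or
non-converging candidate fits are skipped; exactly collinear terms are
aliased to coefficient zero, so a redundant covariate leaves the deviance
unchanged and can never be selected. The bootstrap loop runs through a
compiled (RcppArmadillo) implementation; a plain-R reference implementation
(`engine = "r"`) defines the semantics and the test suite asserts the two
routes select the same panels.

## Validation

For each robust transcript in the independent cohort: group means and their
difference (metastatic-lethal − nonrecurrent), fold change $2^{\Delta}$,
AUC and pAUC on discovery-oriented scores with permutation p-values and
stratified bootstrap CIs, a two-sided Welch t-test, and BH q-values with
the panel as family. The *validated* declaration is: any of the three
p-values below 0.05 **and** q below 0.20. Direction concordance — the sign
of the validation difference agreeing with the discovery orientation — is
tracked separately and not required for validation, matching the design's
reporting. `combined_model()` fits Gleason-only and Gleason+transcript
models on the validation cohort and reports in-sample AUC/pAUC and the
likelihood-ratio test (deviance difference against $\chi^2_1$).

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws, per transcript $g$ and sample $i$,

$$x_{gi} = \mu_g + \delta_g\,[i\ \text{case}] + b_{\text{batch}(i)} + \varepsilon_{gi},
\qquad \varepsilon_{gi} \sim N(0, \sigma_g^2)$$

with $\mu_g \sim U(7, 14)$ (the range of published per-transcript mean log2
intensities in this assay), $\sigma_g \sim U(0.5, 1.0)$ (chosen so that a
planted $|\delta| \approx 0.6$ yields a per-transcript AUC near 0.72 under
the binormal relation $\mathrm{AUC} = \Phi(\delta/\sigma\sqrt2)$, matching
the published effect-size-to-AUC correspondence), 48 planted effects with
$|\delta| \in [0.3, 1.1]$ and about half up-regulated, four plate batches
with $N(0, 0.2^2)$ offsets, and Gleason categories drawn conditionally on
outcome from the observed cohort proportions — so Gleason genuinely
confounds outcome and "improvement over Gleason" is a nontrivial property.
The validation cohort reuses the transcript-level truth (same planted set,
signs, baselines and SDs) with fresh samples, mirroring the
independent-cohort design. Everything is deterministic given the seed;
transcript-level draws depend only on the config seed, sample-level draws
on a seed derived from (seed, cohort).

Deliberately **not** modeled: probe-level cross-hybridization, the two
tissue cores per patient (each patient is one sample; within-patient
correlation is unspecified in this design), censored survival times,
Gleason–expression dependence beyond what outcome induces, and heavy-tailed
or intensity-dependent noise. Passing tests on this generator therefore
demonstrate that the *procedure* behaves as specified under its own
assumptions (calibration, recovery, coverage), not that real FFPE
microarray data satisfy those assumptions.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run the full pipeline at
2,000 transcripts with 20 planted effects ($|\delta| \in [0.6, 1.1]$),
study-sized cohorts (278/27 discovery, 46/32 validation), 200 stability
resamples with `min_count = 8` (the default 40/1000 rate held fixed), 2,000
permutations and 500–1,000 bootstrap replicates. These sizes keep a
complete run in tens of seconds while leaving every rate far from its
decision boundary; the package defaults remain the full-scale settings
(26,051 transcripts, 1000 resamples, 10,000 permutations, 2000 bootstrap
replicates).

## Known limitations

* The union-vs-intersection reading of the dual screening rule, the
  in-sample evaluation of model AUC during selection, and the strict
  `> min_count` robustness inequality are declared conventions; other
  readings of the same design would shift panel sizes.
* The pAUC at 95% specificity is estimated from very few effective samples
  in small cohorts; its bootstrap intervals are wide and its permutation
  p-values coarse. This is a property of the estimand.
* Robust transcripts are validated individually; combining them into a
  single prognostic score is out of scope (and was explicitly deferred in
  the design this package implements).
* `batch_adjust()` removes location/scale batch structure only; batch-by-
  outcome interactions or batch effects confounded with outcome are not
  repairable by any adjustment and must be excluded by design.
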