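---
title: "Rare-CNV gene-set enrichment: model, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-CNV gene-set enrichment: model, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`cnvenrich` tests whether case CNVs hit a gene set more often than
control CNVs, after adjusting for the obvious confounders of rare-CNV
data. The unit of analysis is the CNV, not the subject: each rare CNV
is labelled by its carrier's case/control status, and two nested
logistic regressions are fitted to the pooled CNV sample,

$$\text{logit}\,P(\text{case}) = \alpha + \boldsymbol\gamma\,\text{study}
  + \beta_L \cdot \text{length} + \beta_G \cdot \text{genes outside set}
  \;(+\; \beta_H \cdot \text{hit in set}),$$

with the deviance difference between the two fits referred to the upper
tail of $\chi^2_1$. Under no enrichment the set-hit indicator carries no
information about the label beyond the covariates, and the statistic is
asymptotically $\chi^2_1$; $\hat\beta_H$'s sign distinguishes enrichment
from depletion, which the p-value alone does not.

Assumptions worth keeping in view:

* **Independence of CNVs.** Subjects contributing several CNVs
  contribute several rows. For rare, large CNVs multi-CNV carriers are
  uncommon, but the model does not account for within-subject
  correlation.
* **Asymptotic reference.** The $\chi^2_1$ approximation needs a
  reasonable number of set hits; the hypothesis-free screen's
  ≥ 10-gene-hit rule exists exactly to keep poorly-supported sets out
  of the asymptotic regime.
* **Covariate sufficiency.** Study, length and genes-outside are the
  only adjustments; residual platform differences within a study are
  not modelled.

The same machinery powers every analysis variant: DEL/DUP strata
restrict the rows before fitting; the duplication-versus-deletion test
recodes the outcome to DUP = 1 on case CNVs; gene-wise scans use
singleton sets; the leave-one-study-out analysis refits without each
cohort in turn.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `min_length_bp` | 500 000 | large CNVs are the most reliably called across platforms; 100 000 is the conventional secondary window |
| `mask_max_fraction` | 0.5 | CNVs covered > 50% by common-CNV/segdup masks are likely artefacts or common polymorphisms |
| `max_freq` | 0.01 | the rare-variant boundary; a locus carried by ≥ 1% of subjects is removed |
| `recip_overlap` | 0.5 | 50% reciprocal overlap is the field's conventional CNV-matching rule for locus identity |
| `min_set_genes`, `max_set_genes` | 3, 1500 | screen window: below 3 a "pathway" is a gene pair; above 1500 a set is uninformative |
| `min_hits` | 10 | minimum gene hits in the total sample before a set enters the screen |
| `lambda` | 0.5 | fixed tuning value for the q-value null-proportion estimate |
| hit definition | any 1-bp overlap | footprint overlap is the permissive standard for multi-megabase CNVs; a minimum-overlap fraction is configurable |

Thresholds are read literally: length and mask coverage are strict
(`>`), so a 500 000-bp CNV and a 50%-covered CNV are on the
removed/retained sides respectively, while the frequency rule is
inclusive (exactly 1% is common). Boundary cases are pinned by tests.

## Decisions where the design was open

* **Frequency denominator.** The carrier fraction is computed against
  all subjects pooled across studies by default (`per_study = FALSE`);
  pooling is the conservative choice for rare variants since a locus
  recurrent in one platform's artefact profile still has to clear the
  global bar. Per-study filtering is available.
* **Locus definition.** "Frequency" needs a locus concept; we cluster
  same-type CNVs by single linkage at 50% reciprocal overlap. Single
  linkage errs toward merging, i.e. toward removing more as common.
* **"Most significant single sample".** Defined per tested set, as the
  study with the smallest single-study enrichment p (the study term
  drops out of a one-study fit); the "minus best" result is the refit
  without that study. Ties break lexicographically by study ID.
* **Gene hits for the screen.** Counted as (CNV, set-gene) incidence
  pairs over all CNVs, cases and controls; `distinct_cnvs` mode counts
  set-hitting CNVs instead. Incidence is the stricter reading of "gene
  hits in the total sample" and is the default.
* **Gene-desert CNVs stay in.** The models are fitted to the whole CNV
  sample; CNVs hitting no genes still inform the study and length
  effects.
* **Fixed-λ q-values.** The null-proportion estimate is
  $\hat\pi_0 = \min\{1, \#\{p > \lambda\}/(m(1-\lambda))\}$ at λ = 0.5,
  not the spline-smoothed estimator: deterministic, two lines, and
  adequate for a screen whose validation is property-based. When no p
  exceeds λ the raw estimate is 0 and is floored at $1/m$ so q-values
  stay defined.

## Numerical choices

* Logistic fits run through iteratively reweighted least squares with a
  relative deviance-change tolerance of 1e-10 and at most 100
  iterations. The deviance difference is clamped at zero (numerical
  noise can make the nested difference infinitesimally negative).
* Rank-deficient designs drop aliased columns in reverse entry order
  (the set-hit term enters last, so it is the first candidate), with a
  warning naming the dropped terms. This is checked by explicit rank
  computation, not by trusting a pivoted decomposition's choice.
* Quasi-separation — typical when few hits all sit in cases — is
  flagged when any coefficient exceeds 15 on the scaled design. The
  primary path reports the plain ML fit with the flag; a Firth-style
  penalized refit is available behind `firth = TRUE` and is off by
  default so that default results correspond to the plain
  maximum-likelihood deviance test.
* A constant set-hit indicator means there is nothing to test: the
  statistic is 0 and p = 1, flagged rather than errored, so screens
  over many sets keep running.
* The length covariate is expressed in 100-kb units purely for GLM
  conditioning; the deviance statistic is invariant to this scaling
  (tested to 1e-8) and the coefficient rescales reciprocally.
* Presentation rounding (rates 3 dp, ratios 2 dp, half-up as printed
  tables round) lives only in `format_burden_table()`; computed values
  stay unrounded.
* Result tables are serialised at 6 significant digits so identical
  runs are byte-identical across platforms.

## What the simulators emulate — and what they do not

`simulate_design_rows()` draws covariates (truncated log-normal length,
Poisson genes-outside, Bernoulli set hits) and then the outcome from
the exact logistic model the test fits. It is the reference generator
for calibration: 2000 null replicates of 1000 rows put the empirical
type-I error at α = 0.05 within [0.035, 0.065] and the null p-values
pass a Kolmogorov–Smirnov uniformity test; 200 replicates of 4000 rows
recover an injected $\beta_H$ = 0.7 within ±0.1 with ≥ 90% Wald
coverage. These sizes are the package's validation conditions and are
what `scripts/acceptance.R` reruns.

`simulate_genomic_dataset()` builds a full five-study cohort: the
published cohort sizes, per-study CNV rates near the published
per-study values and each study's duplication share, non-overlapping
genes on a scaled genome (default 10 × 10 Mb, 1000 genes — CNV-gene
geometry depends on local gene density, so a scaled genome preserves
the hit structure at a fraction of the cost), and truncated log-normal
CNV lengths on [500 kb, 5 Mb] with the heavy right tail characteristic
of large-CNV windows. Enrichment is injected at placement: a case CNV
that misses the target set is relocated onto a random target-set gene
with the rejection probability implied by the configured hit log-odds.
Relocation — rather than label flipping — keeps length and gene-count
covariates identically distributed in cases and controls, so any
recovered $\hat\beta_H$ is attributable to the injected hit effect.

What the simulation does **not** model: array-probe-level noise and
platform-specific calling error (the study covariate exists precisely
because real platforms differ), linkage structure and common variants,
gene-length correlation with brain expression, overlapping genes, and
within-subject CNV correlation. Passing the validation suite therefore
shows the statistics are correctly implemented and calibrated under the
stated generative model, not that real CNV calls meet that model.

## Limitations

* Asymptotic p-values only; no permutation alternative is implemented.
* Published headline enrichment p-values for the real five-study data
  are not reproducible here because the individual-level CNV calls were
  never deposited; the published per-study burden counts are built in
  (`adhd_cnv_counts()`) and their rate ratios reproduce exactly. The
  published per-study burden *p-values* came from the original studies'
  own (unspecified) procedures; the conditional binomial test supplied
  here is a documented replacement, not a reproduction.
* Gene annotation is footprint-based; transcript-aware or
  exon-restricted hit definitions are out of scope.
* The q-value implementation intentionally omits the smoothed
  $\hat\pi_0$; published q-values computed with a different $\pi_0$
  scheme will differ even given identical p-values.
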