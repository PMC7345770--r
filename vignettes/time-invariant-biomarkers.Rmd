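---
title: "Discovering time-invariant NGHC biomarkers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering time-invariant NGHC biomarkers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Non-genotoxic hepatocarcinogens (NGHCs) induce liver tumours without
directly damaging DNA, so the in vitro genotoxicity battery misses them
and confirmation requires 2-year rodent bioassays. Short-term rodent
liver transcriptomics is the leading surrogate: treat rats for 1 day to
4 weeks, profile liver expression, and classify chemicals by their
expression response. The catch is that many genes respond transiently —
their NGHC-associated modulation flips sign or disappears between a
1-day and a 1-week exposure, and between laboratories. A biomarker that
is only predictive at the exposure duration it was discovered at is of
limited regulatory use.

`tinvmark` implements a discovery-and-evaluation chain for biomarkers
that are robust in two specific senses:

* **consensus** — the gene is differentially expressed between NGHC and
  non-hepatocarcinogen (NHC) chemicals in *every* dataset at one
  exposure style, with the same direction; and
* **time-invariance** — its modulation direction is the same at *every*
  required exposure style.

## The procedure

### Per-chemical profiles

The unit of analysis is the chemical, not the animal. For a dataset
$d$, exposure style $e$ and chemical $c$, the profile of gene $g$ is

$$ r_{g,c} = \overline{x}^{\text{treated}}_{g,c} -
             \overline{x}^{\text{control}}_{g} $$

on the log2 scale, i.e. a log2 treated-vs-control ratio averaged over
the biological replicates (triplicates in the emulated designs).
Controls are pooled per dataset and exposure by default;
a matched per-chemical control design is also supported because both
occur in the public archives, and `chemical_profiles()` accepts either.

### Differential expression

For each gene, the NGHC chemicals' profile values are compared with the
NHC chemicals' by a two-sided two-sample t-test. A gene is a DEG when
$p < 0.05$ **and** $|\Delta| \ge \log_2 1.5 \approx 0.585$, where
$\Delta$ is the difference of class means on the log2 scale (equality
passes, so the filter is reproducible). Welch's unequal-variance test is
the default because the class sizes are strongly imbalanced (26:62 up to
12:93 in the emulated designs); Student's pooled-variance variant is
available as a sensitivity check. No multiple-testing correction is
applied at this stage: the raw-p-plus-fold-change rule is deliberately
liberal, and specificity comes from the cross-dataset and cross-exposure
intersections that follow. Degenerate genes with zero variance in both
classes get $p = 1$ when $\Delta = 0$ (no evidence) and $p = 0$
otherwise (perfect separation), rather than an error.

### Consensus and time-invariance

At the source exposure style (3-day by default), a gene enters the
consensus set when it is a DEG with the same direction in every dataset
that measures it (a gene absent from one platform is judged on the
datasets that carry it; the requirement can be relaxed via
`min_datasets`). Each consensus gene is then cross-checked at every
required exposure style: its call is "+" when the sign of $\Delta$ is
positive in all datasets at that exposure, "−" when negative in all, and
"+/−" when the datasets disagree. Significance is *not* re-required at
the cross-check exposures — only the direction is examined, which is
what makes a call possible at exposures where the gene was never
selected; a $\Delta$ of exactly 0 evidences no direction and is treated
as disagreement. A gene is **time-invariant** when its call at every
required exposure is "+" or "−" and all calls are equal. The package
ships the published modulation calls of six rat liver biomarker sets
(`read_modulation_calls()`); replaying `modulation_flags()` over them
reproduces every printed yes/no verdict, including the nine-gene 3-day
set (up: Akr7a3, Aqp7, Cdc2a, Cdkn3; down: A2m, Ca3, Cyp2c11, Ntf3,
Sds).

### Classifier evaluation and stability

Features are the per-chemical profiles restricted to the biomarker
genes present on the dataset's platform. Seven classifiers are wrapped
behind one fit/score contract: decision tree (rpart), bagged trees (a
bootstrap aggregate of rpart trees), gradient-boosted trees (xgboost),
k-nearest neighbour ($k = 3$), Gaussian naive Bayes, an RBF-kernel SVM,
and a random forest with `mtry` $= \lfloor\sqrt{p}\rfloor$. Evaluation
is leave-one-chemical-out cross-validation: each chemical is scored by
a model trained on all the others, and the AUC is computed from the
pooled out-of-fold scores by the Mann–Whitney convention (ties count
one half). The random-forest tree count is selected from the grid 10,
20, …, 100 by the same LOOCV, ties broken toward fewer trees; because
selection and reporting share the LOOCV, the selected count's AUC
carries a small optimistic bias, which we accept and document rather
than nesting a second CV the source procedure does not describe.

Stability is summarised over all dataset × exposure runs: the median
AUC and its interquartile range, plus two coefficients of variation that
attribute variance to its source — C.V.d over the per-dataset median
AUCs and C.V.e over the per-exposure median AUCs (both
$100 \cdot \mathrm{sd}/\mathrm{mean}$, sample sd). A signature is
**stable** when IQR $\le 0.05$ on the AUC scale and both C.V.s are
$\le 5\%$. Three conventions are genuinely open and are therefore fixed
and recorded in every report's metadata: quartiles use linear
interpolation between order statistics (quantile type 7); the per-group
summary inside each C.V. is the median, mirroring the emphasis on
median AUC; and the sd uses denominator $n-1$. Boundary comparisons are
non-strict ($\le$), so a report sitting exactly on 0.05 is stable.

For external validation, the model is fitted once on every chemical of
the training dataset and scored on an independent dataset, with features
restricted to the genes the two platforms share.

### Enrichment

Biomarker sets are interpreted by over-representation analysis against
a user-supplied term-to-gene table (e.g. disease–gene associations):
a one-sided hypergeometric tail per term, Bonferroni-corrected over the
tested terms, significant below 0.05. The background defaults to all
annotated genes and can be overridden with the platform's measured
genes; only over-representation is tested, not depletion.

## The synthetic-data generator

No public toxicogenomic archive is bundled, so the generator is a
first-class module that emulates the joint structure of the real
compendia: 2–4 datasets on two platform ID spaces, chemicals labelled
NGHC/NHC at imbalanced ratios (default 26:62), exposure styles from
1-day to 28-day, biological triplicates, pooled or matched controls.
The model is additive on the log2 scale:

$$ x_{g,s} = \beta_g + \delta_{d(s),g} + \theta_{g,e(s)}
             \cdot [\text{NGHC-treated}] + \varepsilon_{g,s} $$

with per-gene baselines $\beta_g \sim N(8, 1.5^2)$ (typical log2
microarray intensities), per-dataset per-gene technical offsets
$\delta \sim N(0, 0.25^2)$, i.i.d. Gaussian noise (default sd 0.5 log2
units), and a planted class effect $\theta$ of magnitude
$\log_2 1.5 \approx 0.585$ by default — the same fold-change convention
the DEG filter uses. Planted genes are of two kinds: *time-invariant*
(constant direction at every exposure) and *time-variant*, in three
archetypes — sign-flip at one random exposure, effect only at early
exposures, effect only at late exposures. "Early" and "late" mean
strictly before and after the midpoint of the exposure ladder (the
first/last $\lfloor E/2 \rfloor$ styles), so the middle style — the
usual 3-day source exposure — carries planted signal only for genuinely
persistent genes and for sign-flip genes, whose reversed call at
another exposure the cross-check must catch. Each platform omits a
configurable fraction of genes (default 5%) to emulate probes absent
from an ID space; datasets sharing a platform share the omission. The
dataset offsets are drawn per simulation: the archives do not
characterise inter-dataset technical variance, so the default magnitude
(0.25, half the default noise sd) is plausible rather than fitted.

What the generator does *not* emulate — and what passing tests
therefore do not establish about real data: probe-level microarray
physics and normalisation artefacts, dose–response structure,
per-animal covariates, correlated gene modules, heavy-tailed noise, and
chemicals with idiosyncratic (per-chemical rather than per-class)
effects. Synthetic classification is also far easier than the real
task: at the parameter-recovery settings the signature separates the
classes almost perfectly (LOOCV AUCs near 1), whereas real compendia
top out around 0.82 — the synthetic runs validate the machinery, not
the attainable performance.

## Problem sizes and determinism

The bundled test and acceptance runs use 2,000-gene simulations with
3 datasets × 3 exposure styles and 130 chemicals (30 NGHC : 100 NHC) in
triplicate — roughly 1,200 arrays per dataset — which exercises every
stage in seconds; recovery is replayed over 20 seeds. A single integer
seed drives the generator and every stochastic learner; within LOOCV
the seed is re-set before each fold, so a fold's score never depends on
another fold's random draws, and identical seeds reproduce runs
bit-for-bit.

## Known limitations

* Direction calls at cross-check exposures use sign unanimity without a
  magnitude requirement; with few datasets, a gene with a near-zero
  effect can occasionally draw a unanimous random sign. The planted
  archetypes avoid placing that configuration at the source exposure,
  but users of very small compendia should read "+/−" rates
  accordingly.
* The RF tree count is selected on the reported LOOCV (optimistic
  bias, documented above).
* A planted effect exactly at the fold threshold (`effect_size =
  log2(1.5)`, the generator default) clears the $|\Delta| \ge \log_2
  1.5$ filter only about half the time per dataset, so an all-datasets
  consensus recovers such genes rarely — the filter is a hard
  threshold, not a power-calibrated test. Recovery benchmarks use a
  clearly supra-threshold effect (1.0 log2 units) for this reason.
* Whether the original archives used matched or pooled controls, and
  per-animal or per-chemical test units, is not recorded; both control
  policies are implemented and per-chemical testing is the default.
* Enrichment reproduces the generic hypergeometric/Bonferroni
  computation; curated annotation content must be supplied by the user,
  and published p-values that depend on a specific catalog version are
  not reproduction targets.
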