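---
title: "Classifier-assisted virtual screening: models, filters and the funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifier-assisted virtual screening: models, filters and the funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenml)
```

## The problem

Structure-based virtual screening ranks a compound library by docking
scores against a target structure and tests the top of the list. Docking
discriminates well between binders and random decoys, but poorly *among*
high-scoring compounds: at the top of a ranked deck almost everything
"looks good" to the scoring function, and experimental hit rates of a few
percent are common. `screenml` implements the remedy this package is
built around: train a binary classifier on known actives and decoys using
*all* the per-compound evidence at once — several docking scores (DS),
pharmacophore fit values (PS) and a large block of molecular descriptors
(MD) — and use it to re-score the final candidates of the screening
funnel, excluding compounds the docking rank alone would have carried
through.

Everything is exercised on a synthetic campaign generator, so the
pipeline is fully testable without licensed docking or pharmacophore
software; real feature tables can be supplied as CSV via
`read_feature_table()`.

## The synthetic campaign generator

`campaign_spec()` + `generate_campaign()` emulate the statistical
structure the analysis assumes, not the chemistry that produces it:

* **Docking scores.** Each compound gets one score per engine/receptor
  channel (default 6: Glide-SP-like, Glide-XP-like and AutoDock-like
  against two chains), drawn as
  `s = mu_engine + effect·label + sqrt(rho)·z + sqrt(1-rho)·eps` with a
  shared latent binding-quality factor `z`. Any two channels then
  correlate at about `rho` (`docking_corr`, default 0.6 — docking engines
  agree substantially but not perfectly), and actives are shifted by
  `docking_effect` (default −2 score units, i.e. two within-class
  standard deviations toward better scores — a strong but realistic
  active/decoy separation on a Glide-like scale). More negative is
  better everywhere; ranking functions take an explicit direction flag.
* **Pharmacophore fits.** A compound maps onto each of 9 pharmacophore
  models with probability `map_prob_active` = 0.95 or `map_prob_decoy`
  = 0.6; failures are encoded as fit = 0 exactly, successes draw from a
  normal truncated at zero (actives mean 2.5, decoys 1.5, sd 0.8 — fit
  values on the usual 0–3-ish scale). Only the failure-equals-zero rule
  is structural; the positive part is a modelling choice.
* **Descriptors.** 1444 columns by default, standard normal marginals,
  with four planted blocks recorded in a truth ledger: 60 informative
  columns (actives shifted by `descriptor_effect` = 1 sd), 150 collinear
  pairs (affine copy plus noise calibrated to sample |r| ≈ 0.96, safely
  above the 0.85 filter cutoff), 120 near-constant columns (one value on
  exactly 95% of rows, safely above the 90% counting threshold — the 5%
  margin avoids boundary flakiness), and 964 pure-noise columns. Real
  descriptor distributions are heavier-tailed and discretised; the
  cascade only consumes moments, correlations and t-statistics, which is
  what the generator reproduces.
* **Fingerprints, rule-of-five profiles.** Compounds inherit a scaffold
  fingerprint (8 scaffolds, 256 bits, 30% density) with 5% per-bit
  mutation, giving the deck realistic cluster structure for the
  similarity operations; MW/logP/HBD/HBA are drawn around typical
  screening-library values so a 15–20% fraction fails the rule of five.

The default 150 actives + 150 decoys match the canonical training-set
size for this kind of campaign. One root seed drives named substreams
per block, so adding a block never perturbs another block's draws, and
identical specs regenerate campaigns bit-for-bit.

What passing tests on these campaigns shows is that the *pipeline logic*
is correct — filters remove exactly the planted redundancy, transforms
never leak validation information, the funnel cannot manufacture
enrichment from noise. It does not certify performance on any real
library, where feature distributions, decoy difficulty and
activity-cliff structure differ.

## The feature-elimination cascade

Descriptor panels are wide (~1460 columns against 300 training
compounds), so the pipeline reduces them in four fixed-order steps,
`eliminate()`:

1. **Counting** (`near_constant_filter()`): drop a column when its most
   frequent value covers *strictly more than* 90% of compounds — a column
   at exactly 90% stays. Exact float equality is deliberate: the filter
   targets discrete/degenerate descriptors, not near-ties.
2. **Correlation** (`correlation_filter()`): |Pearson r| > 0.85 marks a
   pair collinear and the *later* column in table order is dropped, in a
   deterministic greedy scan. Which member to drop is genuinely
   arbitrary; a fixed, order-stable rule makes runs reproducible and is
   cheap to reason about (three mutually collinear columns leave exactly
   the first). The absolute value is used: an r = −0.9 pair is as
   redundant as +0.9.
3. **t-test** (`ttest_filter()`): per column, a pooled-variance
   (equal-variance) two-sample t-test of active vs decoy means; keep a
   column iff its two-sided p ≤ 0.05. Degenerate convention, stated and
   tested: zero pooled variance with differing class means is perfect
   separation, p := 0, retained; with equal means p := 1, removed. When
   nothing at all survives (a fully null panel), `eliminate()` keeps the
   single smallest-p column so downstream fits remain defined.
4. **PCA** (`pca_reduce()`): principal components of the z-scored
   retained columns; keep the smallest number of leading components
   reaching 95% cumulative explained variance, or a fixed `pca_k`. The
   variance-target rule is the package's choice — the count of surviving
   dimensions is data-dependent, and users who need a pinned
   dimensionality can fix `pca_k`.

The report exposes both the pre-PCA retained-column count and the
component count, since "how many features remain" is ambiguous between
the two. Normalisation (`fit_normalizer()`) is mean/sd z-scoring with the
*population* (divide-by-n) standard deviation — the convention is
documented and covered by tests; with batch sizes of hundreds the n vs
n−1 distinction is immaterial. The "batch" is always the training rows
of the current fold, never validation rows.

## Classifiers

Three fixed configurations sit behind `screenml()`:

* `svm_config()` — RBF-kernel soft-margin SVM, C = 1, solver tolerance
  1e-3, shrinking and probability outputs on (libsvm via **e1071**, the
  same solver family scikit-learn wraps). The bandwidth default is
  γ = 1/(d · mean column variance) of the training matrix — scale-stable
  under the z-scoring already applied; γ is configurable.
* `gbt_leafwise_config()` — leaf-wise (best-first) boosted trees with
  depth limit: learning rate 0.1, 10 leaves, depth ≤ 3, ≥ 31 samples per
  leaf, 100 rounds. Implemented with xgboost's `lossguide` growth
  policy; the per-leaf *sample* minimum is mapped to the hessian bound
  `min_child_weight = 31/4` (logistic-loss hessian ≈ 1/4 per sample at
  p = 0.5), the closest available control.
* `gbt_depthwise_config()` — depth-wise boosted trees: 150 estimators,
  depth ≤ 3, min child weight 1, 80% row and 80% column subsampling,
  binary-logistic loss.

`screenml()` always refits the full transform chain (cascade +
normalisation) on its training rows and stores it, so
`predict.screenml()` projects new compounds identically; hard labels use
a 0.5 score threshold by default (the threshold is a field of the model
and can be set per use). `cross_validate()` builds stratified folds by
seeded shuffle plus class-wise round-robin (balance within ±1 compound
per fold; the round-robin continues across classes so leave-one-out
degenerates gracefully), and refits everything per fold — validation
rows never touch any transform statistic, which a dedicated
corruption test enforces exactly. `ablation_compare()` reruns the whole
pipeline per feature-role subset (DS+PS+MD, PS+MD, MD) and classifier,
reproducing the usual input-ablation grid.

All stochastic components (Platt scaling's internal CV, tree
subsampling, fold shuffles) are seeded from the single user seed through
named substreams, so every result in this package is exactly
reproducible.

## Metrics

`roc_auc()` sweeps thresholds over unique scores (ties grouped at one
threshold) and integrates by trapezoid; the result provably equals the
normalised Mann–Whitney pair-counting statistic with half credit for
ties, and the test suite asserts that equality against a brute-force
oracle on random tied instances. `rates()` computes TPR, FPR and ACC as
exact ratios. `separation_pvalue()` is the active-vs-decoy score
separation check; Welch's unequal-variance t-test is the default because
evaluation sets are typically very unbalanced (e.g. 150 actives against
thousands of decoys) — pooled and Mann–Whitney variants are exposed, and
the test is one-sided in the "actives better" direction of the score
convention. `rmsd()` is pose-vs-pose in the shared receptor frame — no
superposition, as appropriate for redocking validation. `hit_rate()` and
`exclusion_rate()` round half away from zero to two decimals at the
reporting layer only.

## The funnel

`run_funnel()` executes the canonical cascade on a deck: rule-of-five
filter → pharmacophore prescreen → SP rank/cut → XP rank/cut (ranked
within the SP survivors, an intersection rule — survivors must score
well at both precisions) → fingerprint leader clustering with
best-consensus-score representatives → optional purchasability mask →
classifier rescoring. Design choices where the workflow is conventionally
manual:

* The prescreen passes a compound iff any fit value exceeds `min_fit`
  (default 0: "mapped at all"); real pharmacophore prescreens are
  geometric and out of scope.
* Leader clustering (deterministic, O(n·k)) replaces hierarchical
  clustering; threshold default 0.6 Tanimoto, configurable. "Manual
  selection of representatives" is modelled as a per-cluster cap with
  best average docking score winning; purchasability is random masking
  at a configurable rate.
* Score ties anywhere break by lexicographic compound id, so reruns are
  stable.

Stage id-sets are nested by construction, and when the deck carries
ground-truth labels the report tracks per-stage precision. On a null
deck (no signal anywhere) expected precision equals deck prevalence at
every stage — the funnel cannot manufacture enrichment, which the test
suite checks by aggregation over seeds.

## Problem sizes used in the checks

The reference checks run the default 150/150 campaign with its full
1459-column table for cascade recovery and cross-validation, a 20-fold
label-permutation null for the AUC floor/ceiling, and ten replicate
2000-compound decks at 5% prevalence (SP cut 300, XP cut 200, up to 20
representatives per cluster) for the rescoring stage. These sizes give
per-stage counts in the hundreds, so the exclusion/retention percentages
they produce are stable to a few points across seeds.

## Known limitations

* Synthetic descriptors are Gaussian; no integer-valued, zero-inflated
  or long-tailed descriptor families, and no activity cliffs.
* Decoys are drawn from the same parametric family as actives (shifted),
  not property-matched the way curated decoy sets are built.
* The pharmacophore and purchasability stages are statistical stand-ins
  for software- and vendor-dependent steps.
* The leaf-wise tree configuration approximates a per-leaf sample
  minimum through a hessian bound (see above).
* `exclusion_rate()` and `hit_rate()` describe a candidate set; they say
  nothing about the compounds a screen never surfaced.

## A minimal session

```{r, eval = FALSE}
spec <- campaign_spec(seed = 1)
train <- generate_campaign(spec)
model <- screenml(campaign_features(train), config = svm_config(), seed = 1)
summary(model)

cv <- cross_validate(campaign_features(train), k = 5, seed = 1)
cv

deck <- generate_screening_deck(campaign_spec(seed = 2), n = 2000,
                                prevalence = 0.05)
report <- run_funnel(deck, funnel_config(sp_cut = 300, xp_cut = 200,
                                         reps_per_cluster = 20,
                                         model = model))
report
```
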