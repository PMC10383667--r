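---
title: "Monte Carlo gene-signature search: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo gene-signature search: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ibdsig)
```

## The procedure and its assumptions

`ibdsig` searches for small sets of genes whose expression separates two
clinical groups in a labeled bulk expression matrix: controls versus
inflammatory bowel disease (IBD) patients, and — within IBD — ulcerative
colitis (UC) versus Crohn's disease (CD). The design is a *wrapper* feature
search: candidate gene subsets are scored by the cross-validated accuracy
of actual classifiers rather than by per-gene statistics alone. The stages:

1. **Encoding.** `label_scheme("control_vs_ibd")` codes control → 0,
   UC = CD → 1; `label_scheme("uc_vs_cd")` codes UC → 0, CD → 1 and
   excludes controls. The positive class is always label 1 (IBD, or CD).
2. **Split.** `split_train_test()` draws a randomized 80/20 partition.
   The training size is exactly `round(0.8 · n)` (half away from zero).
   Stratification by class is the default so both halves contain every
   class; it is best-effort when a class is too small, and subordinate to
   the exact-size contract. Screening and selection see only the training
   half.
3. **Screening.** `correlation_screen()` computes, per gene, the Pearson
   correlation between the gene row and the 0/1 label (the point-biserial
   correlation — the natural reading of "correlation with a binary group").
   `top_q_filter()` keeps the `max(1, floor(q/100 · m))` genes with the
   largest **absolute** correlation. We rank signless because a gene
   down-regulated in disease is exactly as informative as an up-regulated
   one; a signed mode would silently discard half the biology. Ties are
   broken by ascending gene index so the filter is fully deterministic.
   With `q = 1` and m = 56,632 this keeps 566 genes — the floor of
   566.32, which is why the subset rule uses `floor` rather than `round`.
4. **Monte Carlo reduction.** Each of `p_chains` independent chains starts
   from the filtered subset and repeatedly removes a uniform random number
   β ∈ [1, n−1] of genes (`sample_beta()`, `reduce_subset()`). Chains
   restart from the full filtered set rather than continuing one another:
   a single continued chain would exhaust its genes after a handful of
   draws, whereas independent restarts cover subset sizes roughly
   geometrically. At every iteration the whole classifier registry is
   scored by stratified k-fold cross-validation on the training data
   restricted to the current subset, and the best per-iteration result
   enters the candidate pool.
5. **Selection and reporting.** Candidates are ranked by training
   cross-validated accuracy (ties: fewer genes, then algorithm name); the
   top ten are refitted on the full training set and reported with
   held-out test accuracy, sensitivity and specificity. Ranking on CV and
   reporting on test is the only reading consistent with both "the test
   set is not used for model selection" and a leaderboard that prints
   test metrics.
6. **Baselines.** `ann_layer_sweep()` trains one multilayer perceptron per
   depth γ (each hidden layer 30 neurons wide) and keeps the most accurate
   depth (ties → shallowest). `lasso_select()` is the linear
   comparison arm: an L1-penalized logistic regression whose nonzero
   coefficients define the selected genes. `select_best()` takes the more
   accurate of the search winner and the network baseline; an exact tie
   goes to the non-network model (fewer parameters, interpretable splits).

The procedure assumes expression values are already summarized per gene
(no normalization is performed), that samples are independent, and that a
linear correlation screen is an acceptable first-pass noise filter — the
wrapper stage after it is free to exploit non-linear structure.

## The classifier registry

`registry_list()` exposes 23 presets spanning the families a point-and-click
classification tool offers: three tree-complexity tiers, linear/quadratic
discriminants, logistic regression, six SVM kernels, six KNN variants, and
four tree ensembles. The preset names fix the *family*; the hyperparameters
behind them are not published anywhere, so `registry_defaults()` freezes a
conventional table in one place: KNN tiers k = 1/10/100, tree depth tiers
10/5/2, Gaussian-SVM kernel scales √p/4, √p, 4√p, all ensembles 30
learners. Standard fitting goes through the standard packages (`rpart`,
`MASS`, `e1071`, `randomForest`, `xgboost`, `stats::glm`); the pieces with
no R equivalent are written here: a deterministic KNN engine (cosine,
cubic-Minkowski and distance-weighted votes, index tie-breaks), random
subspace ensembles over discriminant and nearest-neighbour learners,
RUSBoost (AdaBoost over class-balanced undersamples), and the multilayer
perceptron (γ × 30 ReLU layers, sigmoid output, full-batch Adam, He
initialisation) — `nnet` stops at one hidden layer, and a depth sweep needs
arbitrary γ.

"Ten times cross validation" is read as 10-fold CV (the convention of the
tools these presets come from), stratified by label so no fold is
single-class at desk scale; `cv_accuracy` is the mean of fold accuracies
and confusion counts are pooled. Quadratic discriminants fall back to a
diagonal-covariance Gaussian classifier whenever the class covariances are
singular (p ≥ class size) — reported as what it is, a well-conditioned
simplification, not silently skipped.

Undefined ratios (specificity of an all-positive test set, for example)
are reported as `NA`, never coerced to 0: a silent 0 would re-rank
leaderboards with fabricated numbers.

Covariates (age, sex, region) are *excluded* from feature matrices by
default: the generator draws them independently of class, so any model
that could see them would be fitting confounding we know is absent. They
remain in the data model for fidelity experiments.

## Randomness and reproducibility

A single master seed fans out to every consumer — split, fold assignment,
chain trajectories, stochastic learners, the lasso's CV folds — through a
deterministic string-hash (`derive_seed()`), so results are independent of
evaluation order and bit-reproducible: the same study, configuration and
seed give byte-identical leaderboard files. Character orderings use radix
sort and fixed level orders, so results do not depend on the session's
collation locale. One deliberate deviation from a literal reading of the
reduction rule: the drawn β is capped at `size − min_size`, so a chain
never overshoots below `min_size` (default 5). Without the cap the final
draw routinely produces 1–2-gene subsets, which are exactly the degenerate
fits the `min_size` floor exists to exclude.

## The synthetic cohort generator

`generate_study()` emulates the structure of a large adult IBD biopsy
cohort: 2,490-case class mix (18.5% control, 35.0% UC, 46.5% CD) by
largest-remainder rounding, ages discretized from a normal (mean 45,
sd 14) truncated to 19–82, sexes at the cohort's observed 47/53 balance,
and seven biopsy regions at their observed frequencies. Expression is
per-gene Gaussian (default mean 8, sd 2, log-scale-like); each of
`n_informative` planted genes has its mean shifted by
`effect_size × baseline_sd` in the positive group of its contrast (IBD
samples, or CD samples; `informative_task = "both"` splits the planted set
between the two contrasts, optionally with different effects). All other
genes are class-independent noise, and covariates are independent of class.

The shipped study conditions, used by the tests and the acceptance script,
are: n = 300 samples, m = 500 genes, 25 informative genes at effect 1.5 SD,
screening at q = 10, 20 reduction chains over a 5-preset registry
(`registry_desk()`), 10-fold CV — sizes chosen so a full search is a
desk-scale computation (tens of seconds) while keeping ≥ 200 training
samples against 50 screened genes. The full protocol (q = 1, 100 chains,
all 23 presets, depth grid to 1000) is reachable through
`pipeline_config()`.

What the generator does **not** emulate — and therefore what passing tests
cannot certify about real cohorts: count-level noise (library size,
overdispersion, zero inflation), gene–gene correlation structure, batch
effects, and confounding between covariates and class (a `confounded`
variant of the last is deliberately absent so that covariate signal, if a
test ever finds one, is itself a detected artifact). Recovery rates on
Gaussian planted signals are an upper bound on what correlated real data
would give.

## Calibration behaviour and known limitations

- **The screening leak is faithful, and visible.** The correlation filter
  is computed on the *whole* training set, and cross-validation then runs
  inside that same training set — the protocol's own ordering. CV
  accuracies after screening are therefore optimistically biased — on pure
  noise cohorts the best CV accuracies exceed the majority rate.
  Held-out test metrics are unbiased; this is exactly why the leaderboard
  reports them.
- **Null calibration of selected models is asymmetric.** On an effect-0
  cohort with the default (imbalanced) class mix, ranking by CV accuracy
  preferentially selects whichever model most overfits the screened noise
  genes. Such a model predicts the minority class at some random rate
  r > 0 on the test set, so its expected accuracy, r·p₀ + (1−r)(1−p₀),
  sits strictly *below* the majority rate p₀ — outside a binomial band
  centred on p₀, which only models that collapse to majority prediction
  (e.g. coarse KNN) stay inside. The package's null-calibration test
  documents this: it is a property of CV-based selection after screening
  under class imbalance, not an implementation defect, and it disappears
  under balanced classes.
- **Preset fidelity is nominal, not bit-level.** The 23 presets mirror a
  commercial tool's families and conventional defaults; no claim is made
  that decision boundaries match that tool.
- **Leaderboards on strong synthetic signal are top-heavy.** With planted
  Gaussian signal, CV accuracy is near-monotone in subset size, so
  iteration-0 (full filtered) subsets dominate the top ten. Real cohorts,
  where small subsets can beat large ones, produce more varied boards.
- **The depth sweep is a baseline, not a tuned competitor.** Networks are
  trained with a fixed budget (150 Adam epochs); the sweep demonstrates
  the depth/accuracy trade-off, and very deep configurations (hundreds of
  layers) are configurable but not part of the shipped conditions.
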