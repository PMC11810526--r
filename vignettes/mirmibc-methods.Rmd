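---
title: "Methods: miRNA-based prediction of muscle invasion with conformal guarantees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-based prediction of muscle invasion with conformal guarantees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Muscle-invasive bladder cancer (MIBC) is treated by radical cystectomy;
non-invasive papillary low-grade tumours (pTa lg) by local resection. The
clinically hard calls are pT1 high-grade (pT1 hg) tumours, which sit between
the two. `mirmibc` implements an analysis chain that asks whether a
four-miRNA qRT-PCR panel (miR-138-5p, miR-146b-5p, miR-155-5p, miR-200a-3p,
normalised against an endogenous control) can classify MIBC versus pTa lg,
attaches a distribution-free certainty guarantee to the classifier via
conformal prediction, applies the frozen model to the ambiguous pT1 hg
group, and relates the markers to luminal/basal molecular subtypes.

No patient-level data ship with the package. Every stage is exercised on a
seeded synthetic-cohort generator that emulates the study design, so all
claims verified by the test suite are claims about the method's behaviour
under that generative model — not about real cohorts.

# The synthetic-cohort generator

`generator_config()` / `generate_cohorts()` model qRT-PCR on the
$\Delta Ct$ (log2 expression) scale. For sample $i$ in phenotype group $g$:

* a reference-assay Ct is drawn, $Ct^{ref}_i \sim N(\mu_{ref}, \sigma_{ref}^2)$;
* a $\Delta Ct$ vector over the panel is drawn from a group-specific
  multivariate normal, $\Delta Ct_i \sim N(\mu_g, \Sigma_g)$;
* target Ct values are $Ct^{ref}_i + \Delta Ct_i$; each assay is measured in
  technical triplicate with independent $N(0, \sigma_{rep}^2)$ noise
  ($\sigma_{rep} = 0.15$ cycles, a typical plate-level spread);
* with probability `dropout_rate` (2%) an assay is "not expressed": its Ct
  is shifted up by 12 cycles, past the Ct 35 filter, rather than deleted —
  so the filtering stage has real work to do;
* pT1 hg samples are a mixture: with probability
  `pt1_mibc_mixture_weight` (default 0.3) a sample is drawn from the
  MIBC-like distribution, otherwise from the pTa-like one;
* every MIBC-like draw carries a latent luminal/basal subtype
  (basal fraction 0.45). Basal tumours shift the miRNA means
  (miR-146b/155 one cycle more expressed, miR-200a one cycle less) and
  drive a seven-marker immunoreactive-score (IRS, 0–12) panel whose
  per-subtype means are 6–9 IRS points apart (4–6 noise sds at
  $\sigma_{IRS} = 1.5$): CK5/CK14/CD44 high in basal, CK20/GATA3/FOXA1/UPK2
  high in luminal.

Default cohort layout: two classification cohorts of 66 and 183 samples
(30/36 and 83/100 pTa lg/MIBC — the per-cohort class split is a choice; the
totals match the study design) plus 120 pT1 hg TURB samples attached to the
larger cohort. The pTa lg and pT1 hg groups are all-TURB; MIBC is 35% TURB.
Three candidate reference assays are emitted: a stable one (miR-361-5p
analogue), a noisier one, and one with a 0.8-cycle MIBC shift that must
fail the reference screen.

Effect sizes are illustrative, not fitted (no data are deposited): the
group shifts were chosen once so that single-marker AUCs qualitatively echo
the published pattern (two strong markers near 0.9, two weak near 0.6), the
between-marker $\Delta Ct$ correlation of 0.6 for miR-146b/miR-155 echoes
the reported expression correlation, and the pT1 mixture weight echoes the
reported one-third MIBC-like calls. None of these values was adjusted after
seeing test outcomes.

What the generator deliberately omits: amplification-efficiency variation,
plate/batch effects, cohort-level distribution shifts, heavy-tailed or
skewed $\Delta Ct$ noise, missing-not-at-random dropout, and correlation
between marker panels and miRNA noise. Passing tests therefore demonstrate
correctness of the machinery and its statistical guarantees under a clean
generative model, and say nothing about real-cohort performance.

Latent truth (generating component, subtype, true $\Delta Ct$, dropout
flags) is emitted in a separate table and never enters the analysis-facing
records.

# Preprocessing

* **Triplicate aggregation** is the arithmetic mean of available
  replicates. Replicates spreading more than 1 cycle are flagged, never
  auto-removed: without a published removal rule any exclusion policy would
  be irreproducible.
* **Expression filter**: strictly `Ct < 35` counts as expressed; a Ct of
  exactly 35 is missing. The filter is idempotent.
* **Reference selection**: among candidate endogenous controls, those whose
  two-sided Mann–Whitney p between pTa lg and MIBC exceeds 0.05 are
  eligible (a reference must not carry group signal); the eligible
  candidate with the smallest Ct variance wins. If none is eligible the
  stage stops and asks for a manual choice.
* **Normalization** is the comparative-Ct method: relative expression
  $2^{-\Delta Ct}$ with $\Delta Ct = Ct_{target} - Ct_{ref}$. Missing
  targets stay missing; samples missing the reference are dropped with a
  logged count.

**Model input scale.** Classifiers consume $-\Delta Ct$ (log2 relative
expression) by default, selectable via `run_config(model_scale=)`. The
relative scale $2^{-\Delta Ct}$ is lognormal under the generative model; a
few large values dominate the per-feature standard deviation, so
standardization compresses the bulk of samples into a tiny region and
Euclidean neighbourhoods degrade. Empirically (same data, same KNN), fresh
pTa lg samples were misclassified about four times more often on the
relative scale than on $-\Delta Ct$. Rank-based statistics are identical on
either scale, so the biomarker tables use relative expression as published
figures conventionally do.

# Biomarker statistics

`mann_whitney()` uses exact enumeration when the combined sample size is at
most 12 with no ties, and the normal approximation with tie and continuity
correction otherwise (the underlying engine is `stats::wilcox.test`; the
test suite pins it against an independent full-enumeration oracle).
`kruskal_wallis()` covers the three-group comparisons. `roc_auc()` computes
the AUC as the pairwise concordance probability (ties count 1/2), which
equals $U / (n_1 n_0)$; curves enumerate all score thresholds. AUCs are
oriented with expression as a score for MIBC, so down-regulated markers
score below 0.5 — the direction, not a deficiency. Following the study's
screening convention, per-marker p-values are reported at the 0.05
threshold without multiplicity correction; treat the single-marker tables
as descriptive.

`feature_correlation()` defaults to Spearman, consistent with the
nonparametric framing; Pearson is selectable since the published
correlation's method is unstated.

# Classifiers

The KNN is implemented natively. Features are standardized with the
training mean and sd only; that transform is frozen into the model.
Probabilities are neighbour-vote fractions over the $k$ nearest training
points under Euclidean distance — exact multiples of $1/k$, summing to 1 by
construction. Two deterministic tie rules: distance ties at the $k$-th
neighbour admit the lower training index (stable ordering), and $k$ must be
odd so the two-class vote cannot tie. Exact probability ties elsewhere in
the pipeline resolve by the canonical class order (MIBC before pTa lg).

The other four families are established implementations behind the same
probability contract: polynomial-kernel SVM (`kernlab::ksvm`,
`prob.model = TRUE`, i.e. sigmoid calibration on internal folds — the
published hyperparameters C, degree, scale map directly onto `polydot`),
single-hidden-layer neural network (`nnet`), random forest
(`randomForest`), and gradient-boosted trees (`xgboost`, depth 3, learning
rate 0.3, which stands in for the boosting-tree family). All stochastic
fits run under a derived seed, so fixed seeds give bit-identical models.
Constructor defaults are the published best hyperparameters where printed:
KNN $k = 19$; VNN size 4, decay 0.01; SVM C = 1, degree 2, scale 0.1.

# Model selection

The protocol: the larger cohort splits, stratified by class, into 2/3
training and 1/3 calibration (rounding per class, so stratification holds
within one sample); the smaller cohort is the untouched test set; pT1 hg
never enters any partition. All $2^4 - 1 = 15$ non-empty miRNA subsets are
crossed with the five families (75 configurations) in a deterministic
canonical order. Hyperparameters are tuned by stratified fivefold CV
maximizing mean out-of-fold AUC; CV ties resolve to the earliest candidate
in canonical grid order. Search grids (the published grid table is not
reproduced in the text, so these are package choices that include every
printed best value): KNN $k \in \{1, 3, \ldots, 31\}$; SVM
$C \in \{0.1, 1, 10\} \times \text{degree} \in \{2, 3\} \times \text{scale}
\in \{0.01, 0.1, 1\}$; VNN size $\in \{2, 4, 8\} \times$ decay
$\in \{0.001, 0.01, 0.1\}$; forest/boosting sizes $\{100, 500\}$.

Evaluation follows the study's conventions: sensitivity is the fraction of
MIBC test samples classified correctly, specificity the fraction of pTa lg;
TURB-only evaluation rescoring just the TURB test specimens mirrors the
pre-surgery decision setting (specificity is unchanged whenever the pTa lg
group has no CYS samples). The leaderboard orders by accuracy, then
sensitivity, then smaller subsets, then canonical configuration order —
the published co-equal best models make an explicit tie rule necessary.
Samples with a missing feature are excluded per configuration with a
logged count; no imputation.

# Conformal prediction

The adaptive-prediction-sets (APS) conformity score of a calibration sample
is the cumulative predicted probability of classes ranked at or above the
true class; in the binary case, $p_{true}$ when the truth is the argmax,
else 1. With $n$ calibration scores the threshold is the conservative
quantile $\hat q = s_{(\lceil (n+1)(1-\alpha) \rceil)}$, clipped to 1 when
the index exceeds $n$. Prediction sets add classes in descending
probability until the cumulative mass reaches $\hat q$, boundary included:
a sample whose top probability is at least $\hat q$ gets a single class,
otherwise both classes with the higher-probability class first. This is the
deterministic (non-randomized) APS variant, matching the published
"greater than or equal to the threshold" rule; the randomized-tie variant
would shrink sets slightly at the cost of non-reproducible outputs.

Two published descriptions of the calibration data ("the remaining third of
the larger cohort" and "one-third of the training cohort") are reconciled
as the same third of the larger cohort, disjoint from training — the only
reading under which training, calibration and test are pairwise disjoint,
which the guarantee requires.

Under exchangeability of calibration and test draws the sets contain the
true class with marginal probability at least $1 - \alpha$. The packaged
Monte-Carlo check (`coverage_experiment()`) freezes a KNN ($k = 19$) on the
122-sample training partition of a default simulation and repeats 500
fresh calibration ($n = 61$) / test ($n = 2000$) draws at
$\alpha = 0.1$. Dropout makes some samples incomplete; complete-case
filtering is applied identically to calibration and test, which preserves
exchangeability. With $k = 19$ the scores take at most 20 distinct values,
so $\hat q$ frequently lands on 1 and coverage is conservative (close to 1
rather than 0.9) while singleton rates stay modest — the expected
behaviour of split conformal with a discrete score.

# Subtyping

IRS panels are Z-scored per marker with the sample-sd ($n-1$) convention
(a documented choice; the published text does not state one); constant
markers become zero columns with a flag. Tumours are clustered by Ward
linkage on Euclidean distances (`hclust(method = "ward.D2")`, the
Ward-criterion implementation for Euclidean input) and cut into two
clusters. The cluster with the larger mean Z over CK5, CK14 and CD44 is
labelled basal — the clustering itself is unsupervised, the label
orientation follows the standard taxonomy. Subtype-stratified miRNA
comparisons reuse the Mann–Whitney machinery and report the median
direction; a three-way Kruskal–Wallis against pTa lg is available for the
supplementary-style comparison.

# Numerical and degenerate-input policy

Errors are classed conditions (`mirmibc_schema_error`,
`mirmibc_config_error`, `mirmibc_model_error`, `mirmibc_conformal_error`,
`mirmibc_stat_error`, `mirmibc_subtype_error`) so callers can
distinguish schema, configuration and numerical failures. Degenerate
inputs have defined outcomes rather than NaNs: identical samples give
$U = n_1 n_2 / 2$, $p = 1$ with a flag; an all-equal Kruskal–Wallis input
gives $H = 0$; a zero-variance feature is a named error at fit time; a
zero-variance marker Z-scores to zeros with a flag; `alpha` outside (0, 1)
and non-positive-semidefinite covariances are rejected up front.

# Problem sizes used by the test suite

The suite verifies oracle equivalence (native KNN vs exhaustive-distance
counting on 200 random instances; exact U-test vs full label enumeration
for all sizes with combined $n \le 10$; AUC vs explicit pairwise
concordance), the coverage experiment at its full size (500 replicates of
61/2000), strong-marker recovery over 50 generator seeds with the KNN
family and a reduced grid $k \in \{5, 11, 19\}$ (the planted-marker
question is about subset ranking, for which one distance-based family
suffices), and exact subtype recovery over 20 seeds. These sizes are the
package's definition of its own checks.

# Known limitations

* All quantitative guarantees are demonstrated under the generator's clean
  multivariate-normal model; real qRT-PCR data bring batch effects and
  heavier tails.
* The conformal guarantee is marginal, not class-conditional (no Mondrian
  variant), and conditional on the frozen model and complete-case features.
* Single-marker tables are uncorrected for multiplicity by design.
* Consensus mRNA-seq subtyping via the external single-sample classifier is
  out of scope; externally produced labels can be supplied to
  `compare_by_subtype()`.
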