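---
title: "Methods: network-hub PLS classifiers and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-hub PLS classifiers and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubclass)
```

This vignette is the package's own account of the statistical procedure it
implements, the choices that had to be made where the underlying methodology
was ambiguous or silent, and what the synthetic validation can and cannot
show.

## The pipeline

The package builds diagnostic classifiers for two-class (tumor vs
non-tumor) expression data in four stages: per-dataset differential testing
with FDR control and cross-dataset intersection; hub selection on an
interaction network spanned by the candidates; a one-component PLS
discriminant over the hub genes with an ROC-derived decision threshold; and
resampling-based validation plus perturbation experiments that isolate the
contribution of network topology.

### Differential candidate selection

Each dataset is tested gene by gene with the pooled-variance two-sample
Student *t* test (`per_gene_ttest()`). The pooled form, rather than Welch's,
is the deliberate default because the procedure this package systematizes is
framed in terms of the classical Student statistic; Welch is available via
`var_equal = FALSE` and matters little at the ~20–35 samples per class
typical here. Genes with zero pooled variance are assigned t = 0, p = 1
rather than NaN, so constant probes can never surface as candidates.

Multiple testing is controlled by Benjamini–Hochberg adjustment
(`bh_qvalues()`, a thin wrapper over `stats::p.adjust`). A π₀-estimating
q-value method would be slightly more powerful but introduces a tuning
dimension; at the conventional q ≤ 0.05 cut-off used throughout, the two
differ negligibly, and BH is deterministic.

`select_candidates()` intersects the per-dataset calls. A gene qualifies as
an up-candidate only if it is significant *with the same direction* in every
dataset — the intersection is performed separately within the up- and
down-regulated lists, which is stricter than intersecting significance
alone and removes genes whose direction flips between platforms. An
optional "concept" gene set (e.g. a cancer gene census) is applied as a
plain intersection.

### Hub selection

Degree (`node_degrees()`) is the number of *distinct interaction partners*:
networks may arrive with directed, signed edges (positive / negative /
unspecified effects, as exported from curated interaction maps), but
direction and sign are treated as annotation only; antiparallel duplicates
collapse and self-loops are removed at ingest.

A node is a hub (`select_hubs()`) when its degree is at least
`min_connections` — default 31, encoding the "more than thirty connections"
rule; the threshold is a parameter because smaller candidate networks
(e.g. the prostate analysis) motivate lower cut-offs — and when fewer than
`max_hidden_fraction` (default 0.5, strict inequality) of its reference
edges are hidden.

"Hidden edges" deserve a note: the term originates in commercial network
software and has no published formal definition. The interpretation adopted
here is that a node's hidden fraction is the proportion of its interactions
in the *global reference network* (the full knowledge base) that are absent
from the candidate subnetwork: `1 − degree_sub/degree_ref`, with the
convention of 0 for nodes isolated in the reference. When no reference
network is supplied the criterion is skipped entirely. This is documented
as this package's reading, not asserted as the original tool's.

### The PLS classifier

With X the n × p matrix of hub-gene expression (samples × genes,
standardized column-wise by *training* mean and SD) and y the 0/1 class
indicator centered to y_c, the one-component PLS weight vector maximizing
cov(Xw, y) under ‖w‖ = 1 has the closed form

> w = Xᵀy_c / ‖Xᵀy_c‖₂.

The per-sample score is S = Σᵢ wᵢ xᵢ (standardized x), a single linear
discriminant. Three choices are configuration rather than dogma, because
the source methodology leaves them open:

* **Components.** The score presented by the method is a single weighted
  sum, so `n_components = 1` (the closed form) is the default. Additional
  components use NIPALS deflation, and the returned weights are always the
  *equivalent single coefficient vector*, rescaled to unit norm, so the
  scoring identity S = Σ wᵢxᵢ holds regardless of component count. At full
  rank this direction coincides with OLS on the standardized predictors
  (verified in the test suite).
* **Standardization.** Predictors are standardized to unit training
  variance. This makes weights comparable across genes and the fit
  equivariant to per-gene scale changes (a property test multiplies one
  gene's raw values by 10 and checks scores are unchanged). Zero-variance
  predictors are dropped with a warning; an all-constant predictor set is
  an error.
* **Threshold.** The methodology calls for "the cutoff at which the area
  under the ROC curve is biggest", which is not well defined — AUC is a
  cutoff-free quantity. The standard single-cutoff optimum on a training
  ROC is Youden's J = sensitivity + specificity − 1, and that is what
  `select_threshold()` maximizes, searching the midpoints between adjacent
  distinct sorted scores plus sentinels below the minimum and above the
  maximum. Ties in J break toward the smallest threshold (the most
  sensitive operating point among equals); the degenerate all-equal-scores
  case therefore yields the low sentinel, calling everything a case with
  J = 0. The decision rule is S ≥ θ → case, with the boundary inclusive.

### Evaluation

`roc_auc()` builds the empirical ROC over all distinct cutoffs (rule:
score ≥ cutoff → case) with sentinel endpoints, and integrates by the
trapezoidal rule, which makes tied case/control scores count one half per
pair — exactly the Mann–Whitney concordance probability. The equivalence is
enforced in the tests against an independent pair-counting oracle.

`repeated_split_eval()` implements the repeated random-split protocol:
per repeat a stratified half/half split (train fraction per class is
configurable; 0.5 is the default as the least-assumptive symmetric reading
of "separated into training and test datasets"), weights *and threshold*
fitted on the training half only, accuracy and AUC measured on the held-out
half, and mean ± SD reported over (by default) 100 repeats. SD rather than
SEM is reported, matching the ± convention of benchmark tables of this
kind; SEM is derivable as SD/√repeats. `kfold_cv()` provides the
complementary stratified 5-fold protocol, returning one ROC per fold.

Both protocols redraw the split every repeat. An alternative reading of
the original protocol — fixing one named test partition and resampling only
the training side — was considered and rejected as less informative; with
redrawing, the reported SD reflects split-to-split variability of the whole
procedure.

### Perturbation experiments

The two experiments in `addition_experiment()` and
`substitution_experiment()` probe whether *hub membership* drives
performance:

* addition keeps all hubs and adds k random non-hubs (k = 1, 2, 4, 6, 8 by
  default);
* substitution fixes the signature size (default 7) and replaces hubs by
  non-hubs along the full ladder 7/0, 6/1, …, 0/7. The full ladder is
  implemented even though the motivating description enumerates only some
  rungs (its list is internally garbled); a superset loses nothing.

Design points worth making explicit: within one repeat every configuration
shares the same stratified split, so comparisons are paired; configurations
are canonicalized internally (hubs descending), making results invariant to
the order in which the caller lists them; and the non-hub pool is an
explicit argument — on real data the natural pool is the candidate genes
not selected as hubs, while synthetic runs may pass pure-noise genes to
isolate the topology effect.

Significance between a configuration and the all-hub baseline is assessed
by a two-sided Fisher exact test on the 2 × 2 table of pooled
correct/incorrect test predictions across repeats
(`compare_performance()`). How the original analysis built its 2 × 2 tables
is unstated; pooling predictions across repeats is this package's
documented construction — it is simple, uses every prediction, and its
power grows with the repeat count, which should be kept in mind when
comparing p-values across protocols with different repeat numbers.

### Clinical statistics

`fisher_exact_2x2()` uses the probability-mass two-sided criterion — the
sum of hypergeometric masses not exceeding the observed table's (relative
tolerance 1e-7 guards floating-point ties) — delegating the computation to
`stats::fisher.test`, which implements precisely this convention; the
exhaustive enumeration oracle in the test suite confirms equality over
random tables with margins up to 30. Zero-margin tables return p = 1 by
convention.

`ihc_composite_score()` encodes the semiquantitative immunohistochemistry
rule: staining graded 0–3 (negative, weak, moderate, strong), composite
score Σ grade × percentage over the graded tumor-cell fractions (range
0–300), and positivity at score ≥ 100, boundary inclusive ("at least 100").
The canonical worked example — 50 % moderate plus 50 % strong staining —
scores (50×2) + (50×3) = 250.

## The synthetic-data generator

Because the original microarray tables are journal supplementary files with
unstated probe mappings, the package ships a generator
(`sim_config()`, `generate_hub_network()`, `generate_expression()`) that
emulates the *statistical structure* the analysis assumes, so that every
downstream claim is testable:

* **Network.** Preferential-attachment growth (m = 2), giving the
  scale-free degree distribution; the `n_hubs` highest-degree nodes are
  designated hubs and topped up with uniformly chosen extra partners until
  each reaches `hub_min_degree` (default 31, so simulated hubs satisfy the
  hub criterion by construction). The graph is connected.
* **Signal.** Per gene a N(0,1) baseline; hubs receive a between-class
  standardized shift of ±`hub_effect` (default 1.5; signs split half up,
  half down, mirroring the two hub classes of the motivating signature),
  a `nonhub_de_fraction` (default 0.1) of non-hubs receive ±`nonhub_effect`
  (default 0.4), the rest 0.
* **Noise.** Per sample, multivariate Gaussian with correlation
  R = I + A/c, where A is the simple adjacency and the loading c is the
  larger of 1/`neighbor_correlation` and a 5 % safety margin over
  |λ_min(A)| (estimated by power iteration; a retry loop escalates c by
  25 % until the sparse Cholesky succeeds, and c > d_max guarantees strict
  diagonal dominance, so termination). This gives *exactly* unit marginal
  variance — scaled by `noise_sd²` — and adjacent-pair correlation exactly
  1/c, i.e. the target 0.3 whenever positive definiteness allows. A
  covariance built instead by normalizing (A + cI) by degree, without
  rescaling to unit diagonal, would make marginal variance depend on
  degree, which would confound hub status with variance — hence the
  correlation-matrix construction.
* **Missingness** is masked uniformly at `missing_rate` (default 0;
  cDNA-style inputs motivate the `impute_and_filter()` step: genes missing
  in more than 30 % of samples dropped, the remainder median-imputed).
* **Reproducibility.** One master seed derives independent sub-streams for
  network, baselines, effects, noise and mask, so changing the sample size
  never perturbs the simulated network. Same seed, same output,
  bit-identical.

Default sample sizes (29 cases, 17 controls) mirror the liver-cancer
dataset that motivated the pipeline.

What the generator does **not** emulate: array-platform artifacts (dye
bias, batch effects, intensity-dependent variance), probe-level structure,
non-Gaussian heavy tails, and any dependence of effect size on degree
beyond the hub/non-hub dichotomy. Passing the synthetic validation
therefore shows the pipeline's statistical machinery is correct and that
the topology phenomenon is recoverable *under the assumed model*; it is
not evidence about any particular real dataset.

### Fixtures and calibration

`make_fixture()` provides three frozen scenarios (fixed internal seeds):
`separable7` (7 strong hubs, 20 + 20 samples, perfectly separable — used
for exactness checks), `paperlike` (29 + 17 samples, default effects), and
`null` (2000 genes, no signal anywhere, 100 + 100 samples).

The null fixture's size deserves a note. Split-resampling summaries
computed on *one fixed* null dataset do not concentrate on 0.5 arbitrarily
fast: the realized chance association between the signature genes and the
labels is frozen into the dataset, giving mean-AUC a dataset-level spread
that shrinks only slowly with n (and a slight downward bias, since
training on one half of a finite null dataset anti-correlates with its
complement). At 100 samples per class this spread is around ±0.04 SD, so
the ±0.1 calibration band used in the tests reflects genuine
miscalibration rather than dataset luck; at 20 per class it would not.

## Problem sizes used by the test suite

The shipped tests run the full pipeline at deliberately moderate sizes —
networks of 100–2000 genes, 29 + 17 to 100 + 100 samples, 100-repeat
protocols, and 20 master seeds for the perturbation phenomenon (~28,000
classifier fits) — chosen so the whole suite completes in a few minutes on
one core while leaving every statistical claim testable at its stated
tolerance. The generator itself handles 10⁴-gene networks (sparse
Cholesky).

## Known limitations

* The hidden-edge criterion implements one defensible reading of an
  undefined commercial term; with no reference network it silently reduces
  to the degree criterion.
* Candidate counts from the original platform snapshot are not
  reproducible (the 2008 database is gone); candidate selection is
  validated on synthetic truth instead.
* The Fisher comparison pools predictions across repeats; repeats share
  the dataset, so the nominal independence of pooled predictions is an
  approximation — its p-values are comparable between configurations under
  the same protocol, but should not be read as calibrated against
  dataset-level resampling.
* No moderated (shrinkage) test statistics, no between-dataset
  normalization, no probe-annotation machinery: probe-to-gene maps are user
  inputs.
* ROC curves are raw and empirical; no smoothing is applied, so curves
  will differ cosmetically from smoothed published figures even when AUCs
  agree.
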