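---
title: "Patient similarity network classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient similarity network classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnpredict)
```

This vignette is the package's account of its own methods: the models it
fits, the parameters that matter, the numerical conventions it commits to,
and the places where the design was genuinely open and a choice had to be
made. The README shows a worked end-to-end example; here we explain *why*
the pieces look the way they do.

## The model

A **patient similarity network** (PSN) is a weighted undirected graph with
patients as nodes. One PSN is built per *feature*: a pathway's worth of
expression measures, one clinical variable, a whole assay, or a pathway's
worth of sparse genetic events. The classifier never sees raw data columns;
it sees networks. This has two consequences that drive everything else:

* **Missing data degrade gracefully.** A similarity can be computed from
  whatever observations a pair shares (pairwise-complete correlation), and a
  patient absent from a layer simply contributes no edges there — the
  integration step uses the networks in which the patient is present.
* **Feature selection is network selection.** A feature is predictive when
  its network connects patients of one class more coherently than expected,
  and the selected networks are directly interpretable.

### Similarity metrics

* `pearson`: weight = Pearson correlation over the group's measures,
  pairwise-complete, **clipped at zero**. Clipping (rather than rescaling
  `(r+1)/2`) is deliberate: integration and label propagation assume
  non-negative affinities, and "anti-correlated" should mean *no* evidence of
  similarity, not half-strength similarity. The choice is exposed via
  `clip_negative`. Pairs with undefined correlation (fewer than two shared
  observations, zero variance) receive no edge.
* `normdiff`: `1 − |x_a − x_b| / (max − min)` for a single continuous
  variable. The range is the *observed* cohort range at build time, not a
  theoretical range: during feature selection networks are built on training
  patients only, so the test cohort cannot leak in through the denominator.
  An all-constant variable has no usable range and is a hard error.
* `binary`: two patients sharing a genetic event in a pathway get weight 1;
  the network is a clique over the pathway's carriers. Pathways with fewer
  than `min_carriers = 6` carriers produce no feature — a near-empty clique
  is one or two edges of pure noise with an outsized chance of earning a
  feature score.

Dense continuous-variable networks can be sparsified (`min_weight = 0.3`,
`max_degree = 50`): drop weak edges, then keep each node's strongest
incident edges, an edge surviving if either endpoint keeps it. The defaults
mirror common similarity-graph practice; the operation is idempotent.

### Feature scoring by regularized integration

For a class with training members \(Q\) and remaining training patients
\(B\), each of `feat_score_max` queries takes a subsample of \(Q\)
(`resample_training()`) and solves

\[ \min_w \; \lVert y - w_0 - X w \rVert^2 + \lambda_r \lVert w \rVert^2,
   \qquad w \ge 0, \]

where rows of \(X\) are unordered patient pairs, columns are candidate
networks (absent edge = 0), and the target \(y\) is +1 for pairs inside the
query sample, −1 for query–background pairs; background–background pairs are
excluded (one-class query semantics — only same-vs-different information
about the query class is used). Negative coefficients are clipped to zero
and the system re-solved on the survivors. A feature's score is the number
of queries in which it kept a positive weight.

Three numerical commitments here were genuinely open:

* **Unpenalized intercept.** The fit includes a constant bias column
  \(w_0\) (never penalized, never clipped). Without it, a network that
  coherently connects training patients of *every* class is punished for its
  strong edges to the held-out members of the query class (those pairs carry
  −1 targets), and at small `feat_score_max` — where a large fraction of the
  class sits in the background — a perfectly discriminative network can be
  clipped to zero. With the intercept the fitted weight tracks the
  *covariance* between edge weight and target, which is the quantity that
  actually distinguishes class-coherent networks from noise.
* **Relative ridge.** The penalty is `ridge * mean(diag(X'X))` over the
  active candidates (default `ridge = 1`). An absolute penalty would make
  the solution depend on the overall scale of the edge weights; the relative
  form makes weights scale as \(1/c\) when all networks are scaled by
  \(c\), so the positive/zero gating that defines feature scores is
  scale-free.
* **Holdout blocks.** Under the `holdout` scheme the class is shuffled once
  per split and cut into `feat_score_max` contiguous near-equal blocks;
  query *i* omits block *i*, so each query uses ≈ `1 − 1/feat_score_max` of
  the class and every member is held out exactly once. With
  `feat_score_max = 1` the single query is the whole class. The
  `montecarlo` scheme instead draws a fixed fraction (default 0.8) per
  query, decoupling the score ceiling from the class size — useful for
  small classes, where holdout would otherwise demand
  `feat_score_max ≤ |class|`.

### Label propagation

Classification solves \((I + \lambda L) f = y\) with \(L\) the combinatorial
Laplacian of the integrated network and \(y\) the indicator of the class's
training members. The system is symmetric positive definite, so the solution
is unique, satisfies the maximum principle
\(\min y \le f \le \max y\), and is computed by conjugate gradients
(relative tolerance `1e-10`, verified against dense direct solves to
`1e-8`). We use this regularized-Laplacian form rather than a
restart-probability iteration because it is closed-form testable and belongs
to the same family of graph-smoothing operators. `lambda = 1` by default;
larger values smooth scores further along the graph.

Selected networks are integrated with **equal weights** for classification:
re-fitting regression weights on a network that already contains test
patients would leak test labels into the model.

Per-class scores are the **normalized rank** (`rank / n_test`, ties
averaged) of the propagation score among test patients, so classes whose
selected networks differ in density and scale remain comparable; exact ties
in the final argmax go to the lexicographically first class — an arbitrary
but documented and deterministic convention. A test patient absent from
every selected network of a class scores 0 for that class with a warning;
this is the missing-data contract, not an error. When no feature reaches
`feat_sel_cutoff` for a class, classification proceeds with that class's
best-scoring feature(s), again with a warning — an explicit fallback chosen
over aborting the split.

## The sparse-genetic workflow

Binary similarity makes feature selection cheap to fool: a clique containing
even one query patient can earn weight. Two countermeasures are built in:

* **Label enrichment.** A network's bias over its members,
  \((n_+ - n_-)/(n_+ + n_-)\), is +1 for an all-case membership, −1 for
  all-control, 0 for balanced. Labels are shuffled over the full cohort
  (membership held fixed — the network's gene content, and hence its member
  set, is not label-dependent) and the empirical p-value uses the +1
  correction \((1 + \#\{b_{perm} \ge b_{obs}\})/(N+1)\), so p is never
  exactly zero and the default threshold `p < 0.07` is meaningful even at
  `num_perms = 20`. There is deliberately no multiple-testing correction:
  the filter is a screen, not an inference.
* **Cumulative scoring.** Feature selection runs `num_splits` times on
  independent held-out fractions (round *k* trains on the other
  `(num_splits−1)/num_splits` of the cohort, stratified), and scores are
  summed, giving a score range of `0 … num_splits × feat_score_max` (e.g. 9
  for 3 × 3, 30 for 3 × 10). Sweeping every cumulative cutoff with the rule
  *case ⇔ event in a selected pathway* yields the per-cutoff
  tp/fp/tn/fn table, from which `perf_calc()` computes trapezoidal AUROC
  (anchored at (0,0) and (1,1)) and step-interpolated area under the
  precision–recall curve (precision at `tp+fp = 0` is defined as 1). Step
  interpolation for PR is the standard unbiased choice; linear
  interpolation between PR points is optimistic.

## Mutation smoothing

`smooth_mutations()` implements random walk with restart:
\(F \leftarrow (1-r)\,W F + r\,F_0\) with \(W\) the column-normalized
adjacency of a binary, symmetric, zero-diagonal gene–gene interaction
network, and \(F_0\) each patient's mutation profile normalized to sum 1.
Isolated genes keep their own mass through a self-loop, so per-patient score
mass is conserved at every iteration (checked to `1e-8`). The restart
probability defaults to `r = 0.5` — an even split between staying near the
seed mutations and diffusing along interactions; smaller values smooth more
aggressively. Convergence is declared when the largest entry change falls
below `tol = 1e-6`.

`binarize_smoothed()` then keeps, per patient, the top
`ceiling(fraction × n_genes)` genes by smoothed score — `fraction = 0.03` by
default — restricted to genes with positive score, ties at the cutoff broken
by gene-name order for determinism, and always unions in the patient's
original mutations: downstream models are built from *direct and inferred*
mutations, and smoothing must never delete observed evidence. Patients with
no mutations pass through as all-zero columns with a warning.

## Integrated PSN and class separation

`aggregate_networks()` combines selected features by the per-pair MEAN
(absent pairs count as 0 and the denominator is the number of networks
aggregated, so a pair present in one network out of three is diluted, not
promoted) or MAX, then optionally keeps the top `top_x` fraction of edges by
weight. `top_x` is interpreted as a fraction of edges network-wide.
`class_separation()` converts weights to lengths as `1/weight` — stronger
similarity, shorter path — runs Dijkstra all-pairs shortest paths, and tests
within-class vs between-class distances per class with a one-sided
Wilcoxon–Mann–Whitney test. Unreachable pairs are excluded and counted
rather than imputed with a pseudo-distance.

## The synthetic-data generator

`simulate_patient_data()` plants class structure the Pearson-profile metric
is designed to detect: each discriminative group carries a class-specific
pattern vector of amplitude `effect_size` on top of unit noise, so
same-class patients correlate over the group and different-class patients do
not. A uniform mean shift would be invisible to a correlation-based metric,
which is why the generator plants *patterns*, not location shifts.
`effect_size = 2` against unit noise is a strong, cleanly recoverable
effect; `effect_size = 0` produces pure noise for null calibration.
`simulate_sparse_events()` plants case-enriched pathways (default event
rates 0.4 in cases vs 0.05 in controls in enriched pathways, 0.05 background)
over disjoint synthetic gene sets.

What the generator does **not** emulate: correlated noise between features
(real pathways overlap and co-express), batch effects, class-imbalanced
missingness, measurement-scale heterogeneity across assays, and linkage
between genetic events. Passing tests on these fixtures demonstrates that
the machinery recovers structure it was designed for and stays at chance
without it — not that any particular clinical dataset will classify well.

One consequence surfaced by the null-calibration tests is worth recording:
with 200 patients and arbitrary labels, a *single* noise dataset carries
accidental alignment between labels and correlation structure worth up to
about ±0.07 AUROC, and every train/test split of that dataset inherits it.
Null behaviour is therefore a property of the dataset-generating
distribution and is estimated over dataset replicates, not from one cohort.

## Problem sizes and tolerances used by the test suite

The suite exercises the full pipeline at sizes a laptop handles in about a
minute: recovery simulations use 200 patients, 20 features × 10 measures and
20 dataset seeds; propagation is verified against dense solves on 100 random
graphs of up to 20 nodes at `1e-8`; enrichment p-values are checked against
exhaustive enumeration on 8-patient cohorts to within Monte Carlo error of
5000 permutations (±0.02); AUROC is checked against the Mann–Whitney
identity exactly. These sizes were chosen to make every stochastic check
comfortably stable under its fixed seed while keeping the suite fast.

## Known limitations

* Two-class and multi-class classification only; no continuous outcomes.
* No probability calibration and no reject option for borderline patients;
  the normalized-rank scores order patients but are not posterior
  probabilities.
* The regression/propagation engine is a deterministic reimplementation of
  the network-integration family of methods, not a bit-compatible port of
  any particular engine; absolute feature scores can differ from other
  implementations even where the selected feature sets agree.
* Label enrichment assumes exchangeable patients under the null; cohorts
  with strong substructure (families, sites) violate this.
* The shortest-path separation statistic treats the integrated PSN as the
  object of interest; its p-values describe that network, not generalization
  error.
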