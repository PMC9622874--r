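---
title: "Methods: from RNA networks to applicability-domain-filtered repurposing candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from RNA networks to applicability-domain-filtered repurposing candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstalkDR)
```

`crosstalkDR` chains five stages: bipartite network hub extraction,
direction-based drug labeling, a four-stage descriptor filter cascade, a
random-forest classifier, and applicability-domain screening of an external
drug library. This vignette records the model behind each stage, the
tunable parameters and their defaults, the numerical choices made where the
design was genuinely open, and what the synthetic benchmark does and does
not demonstrate.

## Hub extraction: whole degree tiers

Both RNA networks are unweighted bipartite graphs; the only centrality used
is degree. "Significant" nodes are chosen by scanning degree tiers from the
top and accumulating *whole* tiers while the cumulative count stays within
`hub_max_nodes` (default 15). Two properties motivated this precise rule:

* Ties are never broken — a tier is taken in full or not at all, because a
  degree cutoff cannot distinguish nodes of equal degree.
* It reproduces both study-scale selections with one default: a 7-node tier
  at degree 4 is taken when the degree-3 tier holds more than 40 nodes, and
  an 11-node selection (3 nodes at degree 7 plus 8 at degree 6) is taken
  when the degree-5 tier holds more than 30.

If even the top tier exceeds the budget, it is returned whole and flagged
(`overflow`), since returning a subset would break the tie-free guarantee.
Isolated nodes (ids mentioned in input lists with no edge, as happens for
disease genes with no recorded miRNA partner) are retained in the node set
with degree 0 and never enter hub selection.

One subtlety matters for recovery experiments: with `k` planted hubs,
exact recovery is guaranteed only at `max_nodes = k`. For larger budgets
the tier rule may legitimately accumulate the next (small) background tier,
so "recovered exactly for any budget ≥ k" is not a theorem of the rule and
the package's recovery tests run the selector at the planted count.

## Drug labeling: signs, contradictions, partition

An lncRNA participates in labeling only when its regulation direction is
known and identical in both diseases. For direction $d \in \{\text{up},
\text{down}\}$ and drug effect $e \in \{\text{increase},
\text{decrease}\}$, the effect sign is

$$\text{sign}(d, e) = \begin{cases}\text{therapeutic} & e \text{ opposes } d\\
\text{exacerbating} & e \text{ reinforces } d.\end{cases}$$

The rule is an involution under the simultaneous flip of both arguments,
which the tests assert. Edges to unknown- or discordant-direction lncRNAs
are *skipped with a warning*, not treated as contradictions: absence of
direction evidence is not evidence of conflict. A drug whose every edge is
unsignable is set aside rather than classified. Duplicate (drug, lncRNA)
records with opposite verbs are refused outright — conflicting source
reports need curation, and any automatic resolution would silently encode
an arbitrary choice. Free-text verbs ("inhibits", "overexpresses", ...)
map to the binary effect through a packaged, extensible vocabulary file.

## The descriptor filter cascade

The cascade reduces a molecules × descriptors matrix to the significant set
F in four fixed stages. Order matters and is part of the method: constant
→ correlated → low-entropy → non-significant.

* **Constant columns** (ignoring missing cells) carry no information and
  break correlation estimates.
* **Correlation pruning** uses the non-exact iterative heuristic over the
  absolute Pearson matrix (pairwise-complete observations): every offending
  pair (|r| > `correlation_cutoff`, default 0.9) flags the member with the
  larger mean absolute correlation (rank-compared, diagonal included),
  without recomputation after drops. This replicates the widely used fast
  mode of the `caret` correlation filter, including its documented
  column-order dependence under ties; the test suite cross-checks the two
  implementations on random matrices.
* **Entropy floor.** Each descriptor is binned into `entropy_bins`
  (default 10) equal-width bins over its observed range and the plug-in
  Shannon entropy is computed in nats; columns below `entropy_threshold`
  (default 1.5) are removed. Natural logs and 10 bins are the conventional
  defaults of the entropy estimator this stage emulates; both are
  config-exposed because neither is canonical. Closed forms anchor the
  tests: a uniform 10-bin column has entropy $\ln 10 \approx 2.303$, a
  two-point 50/50 column $\ln 2 \approx 0.693 < 1.5$.
* **t-test.** Welch's unequal-variance test by default (robust to the
  16/24-style imbalance); the pooled-variance variant is a switch for
  reproducibility attempts. Raw p < `alpha` (default 0.05) with **no**
  multiplicity correction — that is the method being implemented; a
  Benjamini–Hochberg option exists but is off by default, and users
  screening many descriptors should expect ~5% of null columns to pass
  (the type-I rate the acceptance script measures). Rows missing a value
  are excluded from that descriptor's test only; constant-in-pooled-data
  columns get p = 1.

The four removal lists plus F partition the input names exactly, the
cascade is idempotent, and its output is invariant to row permutation.

## The classifier

A random forest (classic Breiman–Cutler implementation) over F. The tree
count defaults to 100; alternatively `n_trees = "auto"` chooses the
smallest forest whose out-of-bag error is within 0.005 of the curve
minimum, making the usual "OOB/forest-size trade-off" reading precise.
Other hyperparameters keep the implementation's defaults (features per
split $\approx \sqrt{|F|}$, unlimited depth) — deliberately: the method
specifies none, and the forest is not tuned.

Cross-validation is stratified by class. With 16 positives and 24
negatives, unstratified 5-fold splits can produce near-single-class folds,
so stratification is a correctness requirement, not a refinement. Overall
accuracy is *pooled* (correct/total over all drugs, each tested once);
the mean of fold accuracies is reported alongside since both conventions
occur in practice. Class probabilities are tree-vote fractions; with a
fixed seed the full CV report is bit-identical across runs.

## Applicability-domain screening

Five ordered, disjoint attrition stages; their counts must always
reconcile to the input size (asserted everywhere):

1. **Atom count**: drugs with nATOM < `natom_min` (default 7) are removed;
   the boundary drug (nATOM = 7) is kept, following the "less than 7"
   phrasing of the rule over the ambiguous "≤ µ" variant.
2. **Missing features**: drugs lacking any value among F.
3. **Leverage**: $h_i = x_i^\top (X^\top X)^{-1} x_i$ with no intercept
   column appended — the +1 in $p = |F| + 1$ enters only the threshold
   $h^* = 3p/n$. By default the basis X is the screened library itself
   (`ad_basis = "screening"`): that is the convention under which the
   published threshold arithmetic $3 \times 7 / 2304$ is reproducible,
   with $n$ the post-filter library size. The textbook QSAR convention
   (basis = training matrix) is available as `ad_basis = "training"`.
   Drugs with $h_i > h^*$ are removed. A rank-deficient $X^\top X$ falls
   back to the Moore–Penrose pseudo-inverse with a warning, since screened
   libraries can contain collinear descriptor blocks; for a full-rank
   basis the implementation is checked against brute-force hat-matrix
   arithmetic (each training $h_i \in [0,1]$, $\sum_i h_i = |F|$).
4. **One-class SVM**: radial kernel on training data standardized by
   training mean/SD, `nu = 0.1`, `gamma = 1/(w \cdot \text{pooled
   variance})` of the standardized block (effectively $1/w$). With only
   ~40 training molecules in a 6-dimensional space the learned boundary is
   tight: fresh in-distribution points are rejected at a rate well above
   the nominal `nu` (which bounds the *training* rejection rate only).
   This is not a defect — comparable attrition (~45% of the in-domain
   library) is exactly what this filter produced at study scale — but it
   means `1 - nu` must not be read as the expected screen retention rate.
5. **Ranking**: each survivor is assigned the class with the larger
   probability; only winners at or above `probability_threshold` (default
   0.95) are reported, sorted within class. The threshold applies to the
   winning class's probability (the method statement does not say which
   class; the max-class reading keeps positives and negatives symmetric).

Because probabilities are vote fractions of a 100-tree forest, a
probability ≥ 0.95 means ≥ 95 concordant trees; even unambiguous molecules
can occasionally fall just short through bootstrap noise. Recovery of
planted strong positives is therefore assessed as "appear in the positive
candidate table, never in the negative one, with a high overall recovery
fraction", not as per-molecule certainty.

## The synthetic benchmark

The generator (`synthetic_spec()` + `simulate_*()`) is first-class, tested
code. Its defaults mirror the study dimensions: a 412-node miRNA layer
with 7 planted hubs, a 1700-node lncRNA layer with 11, a 40-drug effect
table, a 40 × 1444 descriptor matrix with a 16/24 class split, 6
informative columns separated by δ = 3 pooled SDs, 293 constant columns,
400 near-duplicate pairs, 113 low-entropy columns, and a 2474-drug screen
with 4% planted far-outliers (Mahalanobis distance 10), 2% planted strong
positives and 6.3% sub-threshold atom counts (the fraction removed by the
atom rule at study scale). Generation is a pure function of (spec, seed);
every generator returns ground truth alongside its data, and all recovery
tests consume those truths.

Choices worth recording:

* Informative descriptors are Gaussian class-shifted; nuisance noise is
  log-normal. Heavy tails stress the entropy and correlation stages the
  way real skewed descriptor distributions do — and indeed a substantial
  fraction of log-normal noise columns fails the 1.5-nat floor at n = 40,
  as low-entropy descriptors did at study scale.
* "Strong positives" in the screen are drawn around the positive-class
  centroid with 0.25 × the *within-class* covariance. Using the pooled
  covariance would leak the between-class axis into the jitter and plant
  ambiguous molecules.
* Planted network hubs receive exactly `hub_degree` edges; background
  nodes are Bernoulli. Defaults (40 left nodes, hub degree 20, background
  0.15) put the hub tier ~6 SDs above the background degree distribution
  so that tier recovery is essentially deterministic per seed.
* Planted contradictory drugs get one therapeutic and one exacerbating
  edge to two *different* lncRNAs — the same-lncRNA variant would trip
  the duplicate-pair refusal instead of the contradiction logic.

What the benchmark does *not* emulate: real PaDEL descriptor marginals
column-by-column, real interaction-network topology beyond degree
structure, dose/tissue context in effect records, or the identity of any
real molecule. Passing the recovery tests shows the pipeline's logic is
correct under its stated assumptions; it does not validate the biology of
any specific candidate list, which requires the original database
snapshots and descriptor runs.

## Problem sizes and reproducibility

The test and acceptance runs use study-sized rows (40 drugs, 16/24) with
compact planted nuisance blocks (5 constant + 5 correlated pairs + 5
low-entropy + 20–30 noise columns) for the repeated-seed experiments
(100 seeds for hub and cascade recovery, 200 for type-I control, 20 for
end-to-end screening at the full 2474-drug library size), which keeps a
complete run within a few seconds while preserving every dimension that
drives the statistics (row counts, class balance, effect size, library
size). One run seed fans out to per-stage seeds derived by hashing the
stage name, so any stage can be re-run in isolation and reproduce its
in-pipeline result exactly; `run_all()` manifests are identical across
repeated runs up to their timestamp.

## Known limitations

* Feature selection happens once on the full labeled set before
  cross-validation, mirroring the original workflow; CV accuracy therefore
  carries selection bias and should be read as the method's own metric,
  not an unbiased generalization estimate.
* The contradiction rule is purely directional — no effect sizes, doses,
  or tissue context; a drug with weak opposing evidence is removed as
  readily as one with strong evidence.
* With `ad_basis = "screening"`, the leverage threshold depends on the
  library being screened, so the same molecule can pass in one library and
  fail in another; that is inherent to the convention that reproduces the
  published arithmetic.
* The one-class SVM stage's retention rate at n ≈ 40 is governed by
  boundary tightness, not by `nu`; treat its attrition as an empirical
  property of the training-set size.
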