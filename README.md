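# crosstalkDR

Network-guided drug repurposing for the diabetes–Alzheimer cross-talk.

Diabetes mellitus (DM) and Alzheimer's disease (AD) share molecular
dysregulation anchored by brain insulin resistance, and several long
non-coding RNAs (lncRNAs) are dysregulated in the *same direction* in both
diseases. A drug that pushes such an lncRNA back toward normal is a
candidate for repurposing against the cross-talk; a drug that pushes it
further is a warning drug. `crosstalkDR` implements, as tested and reusable
R code, the full workflow from layered RNA interaction networks to a ranked
candidate table:

1. **Network hub extraction.** Bipartite mRNA–miRNA and miRNA–lncRNA
   networks are built from edge lists; "significant" miRNAs and lncRNAs are
   the top *degree tiers*, accumulated whole (never split) while the
   cumulative selection stays within a budget (default 15 nodes).
2. **Drug labeling.** For each lncRNA with a consistent disease direction
   *d* ∈ {up, down} in both DM and AD, a drug effect *e* ∈ {increase,
   decrease} is *therapeutic* iff it opposes *d*. Drugs with both
   therapeutic and exacerbating edges are contradictory and removed; the
   remainder partition into D⁺ (therapeutic) and D⁻ (exacerbating).
3. **Descriptor selection.** PaDEL-style 1D–2D molecular descriptor
   matrices are reduced by a four-stage filter cascade: constant columns,
   pairwise Pearson pruning (|r| > 0.9, dropping the member with the larger
   mean absolute correlation), a Shannon-entropy floor (θ = 1.5 nats over a
   10-bin equal-width histogram), and a two-sample t-test (p < 0.05)
   between D⁺ and D⁻, yielding the significant feature set F.
4. **Classification.** A random forest over F, with out-of-bag error
   guiding the tree count (default 100) and stratified 5-fold
   cross-validation reporting accuracy, precision/recall/F1 and the
   confusion matrix.
5. **Applicability-domain screening.** An external drug library is
   filtered by the atom-count rule (nATOM ≥ 7), leverage
   h_i = x_iᵀ(XᵀX)⁻¹x_i against the warning leverage h* = 3(|F|+1)/n, and a
   radial one-class SVM around the training chemistry; survivors with a
   winning class probability ≥ 0.95 are reported as repurposing candidates
   (positive) or adverse-drug warnings (negative).

A synthetic-data generator (`synthetic_spec()`, `simulate_*()`) produces
networks with planted hubs, effect tables with a controlled contradiction
rate, descriptor matrices with planted informative/nuisance columns, and
screen libraries with planted outliers and strong positives — with ground
truth returned alongside — so the whole pipeline is testable offline.

## Worked example

```r
library(crosstalkDR)

# the packaged 40-drug table: 24 exacerbating, 16 therapeutic
tab5 <- load_fixture("table5_drug_classes")
table(tab5$class)
#> negative positive
#>       24       16

# the applicability-domain threshold for 6 features and 2304 compounds
warning_leverage(6, 2304)
#> [1] 0.009114583   # printed as 0.0091

# a full synthetic study: generate, select features, train, screen
sp  <- synthetic_spec(seed = 11)          # study-scale defaults: 40 x 1444, 2474 screen
man <- run_all(pipeline_config(rng_seed = 11), spec = sp)
man
#> Pipeline run manifest (seed 11, ...)
#>   hubs_mirna                   ...
#>   drugs_labeled                40
#>   input_features               1444
#>   selected_features            ...
#>   cv_overall_accuracy          1
#>   screened_input               2474
#>   screened_retained            ...
#>   candidates_positive          ...
```

The manifest's stage counts reconcile exactly with the stage reports
(`write_screening_report()`, `write_cv_report()`, ...), and the same config
and seed reproduce the run bit-for-bit.

For the model itself:

```r
sim <- simulate_descriptors(sp)
fit <- drug_classifier(sim$matrix, sim$labels, seed = 11)
summary(fit)              # cascade counts, OOB error, feature importance
cv  <- cross_validate(fit$training, sim$labels, seed = 11)
cv                        # fold accuracies, pooled accuracy, confusion matrix
scr <- simulate_screen_library(sp, fit$training, sim$labels)
screen_library(fit, scr$matrix)   # stage-by-stage attrition + candidates
```

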