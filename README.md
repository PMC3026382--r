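# pathmarker

Discriminative subnetwork marker discovery on protein–protein interaction
(PPI) networks, for two-phenotype gene-expression studies.

Single-gene expression signatures for binary clinical outcomes are
notoriously unstable across cohorts. `pathmarker` searches a PPI network for
**subnetworks of interacting genes** whose joint activity separates the two
phenotypes, on the premise that aggregating functionally related genes
yields markers that are both more discriminative and more reproducible.

## The method

Per-gene evidence is a **log-likelihood ratio** under class-conditional
Gaussian fits,

```
α(x) = log σ⁽²⁾/σ⁽¹⁾ − (x − μ⁽¹⁾)²/2σ⁽¹⁾² + (x − μ⁽²⁾)²/2σ⁽²⁾²,
```

and a subnetwork's activity in a sample is the sum of member-gene LLRs; its
discriminative power R is the absolute two-sample t-statistic of that
activity. Candidate **linear paths** λ = (g₁,…,g_l) in the network are
scored by a correlation-weighted sum of member |t|-statistics,

```
s(λ) = |t_α|ᵀ Σ′ J,   Σ′ = (P + (θ−1)I)/(l−1+θ),   S(λ) = s(λ)/l,
```

where P is the Pearson correlation matrix of the members' LLRs and θ ≥ 0
trades individual discriminative power (θ → ∞ gives the mean member |t|)
against inter-member coherence (θ = 0 weights each gene by its average
correlation with the rest). A **beam dynamic program** keeps, for every
node and length l ≤ L, the top-M simple paths ending there (candidates are
fully re-scored — the correlation coupling admits no additive recurrence).
The top m paths of admissible length are **greedily merged**: an
overlapping path joins the subnetwork iff it raises R by more than a factor
(1 + ε). The marker's edges are then cut from the network and the search
repeats, yielding k pairwise-disjoint subnetwork markers.

Evaluation utilities include the classical baselines (top single genes,
average-|t| gene-set ranking, z-normalized mean-expression activity) and a
leak-free **nested cross-validation** harness: stratified 10 folds, a 6/3
split of the training folds into marker-ranking and feature-selection sets,
forward feature selection by strict AUC improvement under logistic
regression, and held-out test AUC plus error-versus-TPR curves.

Because the method's original inputs (genome-scale PPI networks, breast
cancer cohorts) are external resources, the package ships a seeded
**synthetic study generator** — random networks with planted, connected,
differentially expressed and internally correlated modules — used by the
test suite and the acceptance script.

## Worked example

```r
library(pathmarker)

sim <- simulate_study(n_nodes = 120, n_modules = 2, module_size = 5,
                      n1 = 60, n2 = 60, delta = 2, rho_target = 0.6,
                      seed = 101)
cfg <- marker_config(marker_count = 2, length_range = c(4, 6),
                     max_path_length = 6)
fit <- identify_markers(sim$expression, sim$network, cfg)
fit
#> Subnetwork marker set: 2 marker(s), theta = 8
#>    1. 11 genes  R =  27.986  [g0111, g0092, g0069, g0016, ...]
#>    2. 31 genes  R =  17.585  [g0066, g0108, g0117, g0028, ...]

planted <- unlist(sim$truth$modules)
mean(planted %in% unlist(strsplit(summary(fit)$members, ";")))
#> [1] 1

set.seed(1)
nested_cv(sim$expression, fit, n_repeats = 2)
#> Nested CV (2 repeats x 10 folds, llr_sum activity)
#>   mean test AUC = 1.0000 (sd 0.0000 over 20 fold evaluations)
#>   mean features selected = 1.0
```

The two markers recover all ten planted genes (plus neighbouring
background genes whose inclusion still improved R on the training data),
their activity t-statistics (R ≈ 28 and 17.6) dwarf the background scale of
≈ 1, and the cross-validated AUC of the marker-based classifier is 1 on
this clearly separable simulation.

File-level wrappers (`run_simulate`, `run_identify`, `run_score`,
`run_evaluate`) read/write the standard formats (expression TSV + labels
TSV, edge-list/SIF networks, GMT marker sets) and a thin CLI dispatcher
lives at `inst/cli/pathmarker.R`:

```sh
Rscript inst/cli/pathmarker.R simulate --out-dir sim --seed 1
Rscript inst/cli/pathmarker.R identify --expression sim/expression.tsv \
    --labels sim/labels.tsv --network sim/network.tsv \
    --theta 8 --marker-count 3 --out-dir markers
```

See the vignette (`vignettes/subnetwork-markers.Rmd`) for the model,
parameter meanings, numerical choices and limitations.

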