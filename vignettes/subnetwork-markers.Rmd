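---
title: "Discriminative subnetwork markers: model, search and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative subnetwork markers: model, search and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pathmarker)
```

## The problem

Single-gene expression markers for a binary clinical phenotype (for example
metastatic versus metastasis-free breast cancer) tend to be unstable across
cohorts: many genes carry overlapping information, and the top of a
t-statistic ranking changes drastically from one dataset to the next.
`pathmarker` instead searches a protein–protein interaction (PPI) network
for *subnetworks* of interacting genes whose joint activity separates the
phenotypes. Aggregating member genes suppresses measurement noise, and the
network constrains the search to biologically related gene groups, which
empirically makes the resulting markers both stronger and more reproducible
than single genes.

## The model

### Probabilistic activity inference

For each gene $g_i$ the expression level $x_i$ under phenotype
$k \in \{1, 2\}$ is modelled as Gaussian with class-conditional mean
$\mu_i^{(k)}$ and standard deviation $\sigma_i^{(k)}$, estimated from the
phenotype-$k$ samples (unbiased SD, divisor $n_k - 1$). The evidence a
measurement carries about the phenotype is its log-likelihood ratio (LLR)

$$\alpha(x) \;=\; \log\frac{f^{(1)}(x)}{f^{(2)}(x)}
  \;=\; \log\frac{\sigma^{(2)}}{\sigma^{(1)}}
  \;-\; \frac{(x-\mu^{(1)})^2}{2\,\sigma^{(1)2}}
  \;+\; \frac{(x-\mu^{(2)})^2}{2\,\sigma^{(2)2}},$$

positive when the observation favours phenotype 1. The *activity* of a
subnetwork $G_s$ in a sample is the plain sum of its member-gene LLRs, and
its *discriminative power* $R(G_s)$ is the absolute two-sample t-statistic
of that activity between the phenotypes. The sum is not rescaled by the
member count: t-statistics are scale-invariant, so a $\sqrt{n}$
normalization would change no ranking.

Class-conditional SDs are floored at $10^{-6}$ times the global SD of the
expression matrix, so a gene constant within one class yields large but
finite LLRs instead of infinities. The t-statistic is Welch's
unequal-variance form by default; the pooled-variance Student form is
available via `marker_config(var_equal = TRUE)` for compatibility with
classical average-t ranking schemes.

### Scoring linear paths

Candidate building blocks are *linear paths*: ordered, duplicate-free gene
sequences whose consecutive members interact in the PPI network. A path
$\lambda = (g_1,\dots,g_l)$ is scored by a weighted sum of its members'
absolute LLR t-statistics $|t_\alpha(g_i)|$, with weights derived from the
Pearson correlation matrix $P$ of the members' LLRs (all samples pooled,
signed correlations):

$$s(\lambda) \;=\; |\mathbf{t}_\alpha|^\top \,\Sigma'(\lambda)\, J,
\qquad
\Sigma'(\lambda) \;=\; \frac{P + (\theta - 1) I}{\,l - 1 + \theta\,},
\qquad
S(\lambda) \;=\; \frac{s(\lambda)}{l},$$

where $J$ is the all-ones column vector. The trade-off parameter
$\theta \ge 0$ balances individual discriminative power against coherence:

* $\theta = 0$: each gene is weighted by its average LLR correlation with
  the other members — coherence dominates;
* $\theta \to \infty$: $\Sigma' \to I$ and $S$ becomes the plain mean
  member $|t_\alpha|$ — individual power dominates;
* $l = 1$: $\Sigma' = [1]$ for every $\theta$, so a singleton path scores
  exactly $|t_\alpha|$.

The division by $l$ makes $S$ comparable across lengths: for a perfectly
coherent path (all pairwise correlations 1) $S$ equals the mean member
$|t|$ at *every* $\theta$, an algebraic identity of the weight matrix that
the tests verify. Absolute t-scores are used throughout, so up- and
down-regulated genes mix freely in one path; the LLR transform reorients
down-regulated genes, making their LLRs positively correlated with those of
up-regulated partners.

One property worth knowing: for *incoherent* members (correlations near 0)
the weight row-sums are $\theta/(l-1+\theta) < 1$, so the expected null
score shrinks mildly with length at finite $\theta$. The normalization is
therefore conservative — long paths are never rewarded for length alone,
and the effect vanishes exactly for the coherent paths the search is
designed to find. The default exponent in $S = s/l^{e}$ is $e = 1$, the
choice under which the $\theta \to \infty$ score is the mean member $|t|$;
$e = 2$ is available via `marker_config(norm_exponent = 2)`.

### Dynamic-programming beam search

Exhaustive search over simple paths is infeasible on genome-scale networks,
so the package uses a beam-style dynamic program. For every node $v$ and
length $l$ (counting nodes; $l = 1$ is the singleton), a table cell keeps
the $M$ highest raw-scoring simple paths of length $l$ ending at $v$.
Length-$l$ candidates arise by appending $v$ to the length-$(l-1)$ paths
stored at its neighbours (skipping those already containing $v$). Because
the correlation coupling makes the score non-additive, no score recurrence
is assumed: every candidate is re-scored exactly, using one precomputed
gene-by-gene LLR correlation matrix so each evaluation is $O(l^2)$.

The beam is exact whenever $M$ is at least the number of simple paths per
(node, length) — every simple path extends a simple path at a neighbour —
which is how the tests validate it against exhaustive enumeration on small
graphs. Ties in the raw score are broken by the lexicographic order of the
gene-identifier tuple, making the whole search deterministic. Stored paths
are orientation-free at collection time: a path and its reversal score
identically and are deduplicated.

### Greedy assembly and iteration

The top $m$ paths whose length lies in `length_range` are pooled, sorted by
$S$, and merged greedily: the best path seeds the subnetwork $G_s$; each
remaining path is scanned once in rank order; a path sharing at least one
gene with the *current* $G_s$ is tentatively unioned, and the union is kept
iff

$$R(G_s \cup \lambda_i) \;>\; (1 + \epsilon)\, R(G_s),$$

with $R$ recomputed from the summed-LLR activity each time. The strict
margin $\epsilon$ (default 0.01) guards against overfitting the merge
decisions to the training data. A path disjoint from $G_s$ at its turn is
not revisited; `marker_config(multi_pass = TRUE)` enables rescanning until
no merge is accepted, for users who want the variant.

After a marker is emitted, every edge incident to its members is removed
from the network and the search repeats, so the $k$ markers are pairwise
disjoint by construction. When the admissible path pool empties before $k$
markers are found, the run returns what it has with a warning rather than
failing — small networks exhaust quickly.

## Defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| `theta` | 8 | power-vs-coherence trade-off; 8 balances the two well in practice |
| `max_path_length` | 8 | DP horizon, in nodes |
| `beam_width` (M) | 20 | paths kept per (node, length) |
| `top_paths` (m) | 100 | pool size for greedy assembly |
| `length_range` | [5, 8] | admissible path sizes; markers then grow by merging |
| `epsilon` | 0.01 | strict relative improvement a merge must exceed |
| `marker_count` (k) | 50 | markers requested per dataset |

Path "length" counts nodes, so the singleton case $l=1$ anchors the DP
initialization at $s = |t_\alpha|$; the admissible window $[5, 8]$ is
expressed in the same units.

## Evaluation harness

`nested_cv()` evaluates a *fixed* marker catalogue (discovery is not re-run
per fold, which mirrors common practice but is a known optimistic bias —
callers comparing methods should apply the same protocol to each):

1. stratified 10-fold split; one fold held out as the test set;
2. the 9 training folds are split 6/3 into a *marker-ranking set* and a
   *feature-selection set* (a seeded stratified draw — the assignment is
   not rotated);
3. Gaussian/LLR parameters (or mean-expression normalizers) are estimated
   on the 9 training folds only, so test samples never touch them;
4. markers are ranked by activity $|t|$ on the ranking set, the pool capped
   at the top 50;
5. forward selection: starting from the top marker, each next marker is
   kept iff the logistic-regression AUC on the feature-selection set
   *strictly* increases;
6. the selected model's AUC on the test fold is recorded; means are
   reported over repeats × folds, along with a pooled error-versus-TPR
   curve (for each target sensitivity, the smallest achievable overall
   error among admissible thresholds).

The AUC is the rank-based (Mann–Whitney) estimator with ties counting one
half. Logistic regression is unpenalized `stats::glm`; with at most 50
features and hundreds of samples this is stable, and perfect-separation
warnings on synthetic data are harmless because only the score ordering
enters the AUC. Baselines mirroring the literature are provided:
`gene_marker_baseline()` (top covered genes by $|t_\alpha|$ as singleton
markers), `average_t_ranking()` (mean member $|t_\alpha|$, the classical
pathway-ranking scheme), and `mean_expression_activity()` (z-normalized
mean member expression, the averaging-style activity; normalization uses
training samples only inside CV).

## The synthetic study generator

Real PPI overlays are external resources, so the package ships a seeded
generator that emulates the statistical structure the method assumes:

* a random network (Erdős–Rényi by default, mean degree 4; optionally
  Barabási–Albert) of a few hundred nodes;
* planted pairwise-disjoint *connected* modules grown by random walks
  (edges are added, and reported, only if growth stalls);
* expression in which a planted gene of module $q$ takes
  $s_g\,(\delta_q/2)\,c + b_q z + \mathcal N(0, \sigma^2)$, with $c = \pm 1$
  the class code, $s_g = \pm 1$ a per-gene orientation (a quarter of
  planted genes are down-regulated by default, exercising the
  mixed-orientation capability), and $z$ a per-sample latent factor shared
  within the module. The loading $b_q$ is solved from the target
  within-module LLR correlation
  $\rho = (\delta^2/4 + b^2)/(\delta^2/4 + b^2 + \sigma^2)$; targets below
  the $b = 0$ floor $(\delta^2/4)/(\delta^2/4+\sigma^2)$, or $\ge 1$, are
  rejected with the feasible range. The latent construction keeps the
  generator linear in genes × samples and the implied covariance positive
  semidefinite by construction.

The standard study used by the tests and the acceptance script — 300
nodes, 3 modules of 6 genes, $\delta = 2$, $\rho = 0.5$, 100 + 100 samples
— runs the full pipeline in seconds and is comfortably recoverable: the
planted per-gene $|t|$ is ≈ 14 while background genes sit near 1. What
passing these tests shows is that the machinery (inference, search,
assembly, validation) is correct and calibrated; it does *not* show that
the method handles microarray-specific artefacts — probe effects, heavy
tails, missing values, batch structure — which the generator deliberately
does not model.

## Numerical and design notes

* **Degenerate variances.** Per-gene/class SDs are floored (see above);
  degenerate t-statistics (zero spread in both classes) return 0 with a
  warning rather than NaN; zero-variance LLR rows correlate 0 with
  everything by convention.
* **Determinism.** Given identical inputs and seed, discovery output is
  byte-identical; all stochastic steps (simulation, fold draws) flow from
  user-provided seeds.
* **Tie-breaks.** Score ties in the DP and in every ranking break on
  lexicographic identifiers, never on memory order.
* **Disjointness guard.** Pruning removes edges (members become isolated),
  which suffices for disjoint markers whenever `length_range` starts at 2
  or more; collected paths touching previously assigned genes are filtered
  as well, so even `L_min = 1` configurations cannot resurrect a used gene.
* **Problem sizes.** The bundled tests use networks of 60–300 nodes and
  60–200 samples; exhaustive-enumeration oracles run on ≤ 11 nodes where
  enumeration is exact. These sizes were chosen as the smallest at which
  every claimed property is measurable with comfortable margins.

## Limitations

* Two phenotypes only; no multi-class generalisation is attempted.
* Identifiers must be pre-matched across expression and network (no probe
  → gene → protein mapping).
* Marker discovery inside `nested_cv()` is fixed, not re-run per fold; the
  reported AUC is an optimistic estimate of fully external performance.
* The exact weight-matrix formula and normalization exponent of the
  original scoring scheme admit more than one reading; the implemented
  $\Sigma'$ is the simplest form satisfying the known limiting cases, and
  both are exposed as configuration (`norm_exponent`) or documented
  behaviour rather than hidden constants.

## A worked micro-example

```{r example}
sim <- simulate_study(n_nodes = 120, n_modules = 2, module_size = 5,
                      n1 = 60, n2 = 60, delta = 2, rho_target = 0.6,
                      seed = 101)
cfg <- marker_config(marker_count = 2, length_range = c(4, 6),
                     max_path_length = 6)
fit <- identify_markers(sim$expression, sim$network, cfg)
fit
summary(fit)[, c("marker", "size", "R", "n_paths")]

# how much of the planted truth was recovered?
planted <- unlist(sim$truth$modules)
mean(planted %in% unlist(summary(fit)$members |> strsplit(";")))

set.seed(1)
nested_cv(sim$expression, fit, n_repeats = 2)
```
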