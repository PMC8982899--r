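---
title: "From single-drug profiles to ranked synergistic combinations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From single-drug profiles to ranked synergistic combinations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omusynergy)
```

# The problem

Testing every two-drug combination in a dose–response matrix experiment is
quadratic in the number of drugs and is the bottleneck of combination
screening. This package implements a network-based shortcut: it uses only
*single-drug* data — one transcriptomic profile per drug plus each drug's
maximal growth-rate inhibition (GRmax) — to rank all pairwise combinations
by their predicted joint impact on growth, so that wet-lab dose–response
validation can be concentrated on a small top list.

The chain of models is:

1. one weighted bipartite TF→gene regulatory network per condition,
   inferred by message passing over a regulatory prior, TF–TF protein
   interactions and gene co-expression;
2. per-drug *differential gene modules* against the untreated network,
   scored by a differential-modularity matrix;
3. an *operational module unit* (OMU) system pooling similar modules
   across drugs, each OMU carrying a shared edge structure, its member
   modules and a mean GRmax;
4. each drug as a sparse non-negative vector over the OMU system,
   analysed compositionally: an isometric log-ratio (ILR) balance at an
   internal node of the OMU hierarchy is regressed on GRmax;
5. combined pair vectors (component-wise maximum, renormalized), their
   predicted growth impact score (GIS), and a differential growth impact
   score (DGIS) comparing each pair with its two self-pairs;
6. optional validation: ZIP synergy scores of 6×6 dose–response matrices
   and a two-trial maximum-likelihood enrichment statistic.

# Network inference

`infer_grn()` integrates three data sources restricted to their common
TFs and genes (intersection behavior): the prior `W0` (TF×gene), the PPI
`P` (TF×TF) and co-expression `C` (gene×gene), each normalized by
row/column z-scores. Each iteration computes a *responsibility* term
`T(P, W)` (do interacting TFs agree about a target?) and an
*availability* term `T(W, C)` (do co-expressed genes share a regulator?),
where `T` is the continuous Tanimoto similarity
`T(A,B)_ij = (AB)_ij / sqrt(|A_i|² + |B_j|² − |(AB)_ij|)`. The weight
matrix moves toward the average of the two messages with update step
`alpha = 0.1`, and `P` and `C` are nudged toward the TF–TF and gene–gene
similarity implied by the current `W` at the same rate.

Two numerical points matter:

* **Annealing.** After each `P`/`C` update the diagonal is re-inflated to
  `(off-diagonal row sd) · n · exp(2·alpha·iter)`. The growing
  self-similarity damps the messages over iterations, so the fixed point
  retains the graded, data-driven structure of the early iterations. We
  found both obvious alternatives fail: without any stabilizer the
  co-update feedback diverges exponentially, and re-standardizing every
  matrix each iteration drives the system into a saturated ±1 attractor
  that erases within-block gradation.
* **Convergence** is declared when the mean absolute difference between
  the weight matrix and its message proposal falls below `1e-3` (at most
  200 iterations; the last iterate is returned with a warning flag
  otherwise). The final matrix is z-scaled over all entries. The
  procedure involves no randomness, so identical inputs give bit-identical
  networks.

With a single profile per condition, co-expression cannot be computed per
condition. The pipeline therefore computes one pooled co-expression
matrix from all conditions and adds, for each drug, a rank-one term built
from the drug's expression deviation from control
(`condition_profile`), scaled by `condition_weight` (default 1). This is
what makes the per-condition networks differ; the control condition uses
the pooled matrix unchanged.

# Differential modules

`baseline_partition()` finds communities of the untreated network by
weighted Louvain optimization on the bipartite graph (seeded, with
community labels canonicalized by size then smallest node id). Modularity
machinery needs non-negative weights, so z-scored networks are shifted by
a single constant — the global minimum across the study's networks —
applied identically to both conditions, which preserves ordering.

`differential_modularity_matrix()` treats the baseline partition as a
stochastic-block null for *change*. For the TF–gene pairs of each
baseline community pair (Ci × Cj), the expected treated weight is the
control pattern rescaled to the treated block total; the differential
modularity is the observed excess, floored at zero:

```
D = max(0, w_t − w_c − e_conf · (rho − 1)),
e_conf = s_c(tf) d_c(g) / W_c  (within Ci × Cj),  rho = W_t / W_c.
```

This definition keeps three contracts that guide all tests: comparing a
network against itself gives `D = 0` everywhere; scaling both networks by
a constant scales `D` by that constant; and a single strengthened edge
becomes the matrix maximum. Because every community *pair* is scored,
coherent rewiring *between* baseline communities — where, in our
synthetic studies, most drug signal concentrates — is captured, not only
redistribution inside a community.

`extract_differential_modules()` runs seeded Louvain on the graph whose
edge weights are the positive entries of `D`; a module keeps the edges
internal to one community (hence modules are edge-disjoint), needs at
least `min_edges = 2` edges, and carries its `D` entries as per-edge
scores whose sum is the module weight.

# The OMU system

Modules from different drugs are compared by the edge-set Jaccard index.
All cross-sample pairs with `J ≥ min_similarity` (default 0.25) are
visited in descending similarity (ties broken by pair id, with
zero-padded module indices so the order is total). Each pair's shared
edge set either extends the existing OMU whose structure it matches best
(provided that match itself reaches the threshold; the structure then
narrows to the intersection, increasing specificity) or founds a new OMU.
Modules that never pair become singleton OMUs with their full edge set. A
module may belong to several OMUs.

The mean GRmax of an OMU with member modules *i* is
`Σ GR_i·X_i / Σ Y_i`, where `X_i` is the member's module weight and
`Y_i` the total module weight of that member's sample: each member
contributes its sample's GRmax in proportion to the module's share of the
sample's differential signal, which bounds the result by the member
GRmax range. Among the index conventions one could adopt for the
denominator, this is the one that keeps the quantity a proportional
GRmax in [−1, 1].

A drug's OMU vector assigns each OMU the summed weight of the drug's
member modules there (`weights = "module"`, the default, matching the
verbatim definition of the vector). A structure-restricted variant
(`weights = "structure"`) that counts only the module edges inside the
OMU structure is provided for sensitivity analysis; on synthetic studies
it recovered the GRmax relation consistently worse, which is why it is
not the default.

# Balances and the linear model

OMUs are clustered by average-linkage on |Δ mean GRmax| (input order
canonicalized, so the tree is permutation invariant; at every internal
node the left subtree has the lower centroid). The ILR balance of a
vector at a node contrasts the geometric means of its left and right
components:

```
b = sqrt(nL·nR / (nL + nR)) · ln( g(left) / g(right) )
```

Sparse vectors make zeros the central numerical decision. Two modes are
implemented:

* **positive-part** (the `ilr_balance()` default): geometric means over
  positive components only, with `nL`, `nR` counting them; a side without
  positive components makes the balance an explicit `NA` sentinel;
* **pseudocount** (the *pipeline* default, `pseudocount = 1e-4`): vectors
  are converted to proportions and a fixed epsilon is added to every
  component, so every balance is defined and an *absent* OMU pulls its
  side down through the replacement value.

The pipeline defaults to the pseudocount because in sparse vectors the
presence/absence pattern itself carries most of the phenotype signal;
positive-part balances discard exactly that information, and on synthetic
studies they left many drugs undefined at most candidate nodes. The
epsilon sits well below the smallest observed proportion of a present
OMU, and balances are invariant to vector scale in both modes.

`select_balance_point()` restricts candidates to internal nodes with
centroid mean GRmax in [−0.5, 0.5] and with defined balances for at least
90% of drugs, and picks the candidate maximizing |Pearson r| between
balances and GRmax (ties: deeper node, then smaller id). A `use_root`
switch skips the search and uses the root, the reading in which every OMU
participates. `fit_linear_model()` is ordinary least squares of GRmax on
the balance, reporting slope, intercept, r and R².

# Combination scoring

A pair's combined vector takes the component-wise maximum of the two
single-drug vectors and renormalizes to proportions; `combine = "sum"` is
available for sensitivity analysis. The maximum is the operative rule:
each drug is assumed to drive a shared OMU at least as strongly as it
does alone. Combining a vector with itself reproduces its own
proportions, which anchors the self-pair identity chain: idempotent
combination → equal GIS → zero DGIS, exactly.

GIS is the model prediction `intercept + slope · b` at the fitted node —
unbounded, unlike GRmax. DGIS compares a pair's GIS with its two
self-pair GIS values: below both it is the (negative) gap to the lower
one, between them (inclusive) zero, above both the (positive) gap to the
higher one. Ranking is ascending DGIS with ties broken by GIS and then
lexicographic pair order; the default list keeps the top 30.

# ZIP validation and enrichment

`zip_synergy()` fits four-parameter logistic curves to the two
monotherapy margins of a 6×6 matrix (bounded Levenberg–Marquardt with a
multi-start over slope and midpoint; non-convergence falls back to
monotone interpolation), forms the Bliss independence surface of the
fitted margins `y1 + y2 − y1·y2`, and reports the mean observed-minus-
expected delta over the 25 interior cells, ×100. The score is on the
percentage-point scale — the scale on which the conventional `> 5`
synergy call operates — and a matrix equal to its own Bliss expectation
scores 0 to machine precision of the fit.

The enrichment argument treats the top-k list and a random draw as two
trials with a common unknown proportion M of truly synergistic pairs and
maximizes the joint probability. Under the binomial model the argmax is
the pooled proportion `(k1+k2)/(s1+s2)`, verified numerically; a
finite-population (hypergeometric) variant maximizes over the integer
number of synergistic pairs in the population and is reported alongside,
since the two models' joint probabilities differ while their argmax
proportions nearly coincide.

# The synthetic-study generator

`simulate_study()` emulates the statistical structure the analysis
assumes, with all randomness derived from one integer seed:

* a block-structured regulatory prior (7 blocks by default over 30 TFs
  and 200 genes; within-block TF→gene edge probability 0.7 vs 0.03
  across) and a PPI denser and stronger within blocks;
* a drug design in which two blocks are death-associated, every drug
  perturbs one primary block (death with probability 0.4), one random
  neutral secondary block, a stress block whose magnitude grows with the
  drug's kill signal, and a housekeeping block perturbed independently of
  phenotype — so every drug's regulatory footprint spans both
  death-associated and neutral programs, as the balance analysis
  requires;
* log-scale expression: baseline N(8, 1) plus the block magnitudes times
  per-gene loadings with 30% per-drug response jitter and N(0, 0.3)
  profile noise — levels chosen so that within-block co-expression is
  strong but graded rather than degenerate;
* GRmax = 0.9 − 1.1 × (summed death-block magnitude) + N(0, noise_sd),
  clipped to [−1, 1];
* per-drug 4PL inhibition curves whose plateau is `(1 − GRmax)/2`, and
  combination matrices following the Bliss expectation plus a constant
  planted interaction on interior cells for designated synergy pairs.

Members of a planted synergy pair perturb *complementary* death blocks,
so their combined vector accumulates more death-side mass than either
self-pair — the transcriptional counterpart of the planted dose–response
interaction.

What the generator does **not** emulate: landmark-gene inference,
plate/batch artifacts, dose-dependent expression, correlated noise, or
drugs with off-target profiles unrelated to their phenotype. Passing
tests therefore show that the pipeline recovers the intended signal when
the modelled structure is present, not that it will do so on any real
dataset.

# Test problem sizes

The test suite exercises the full pipeline at 20–30 drugs, 30 TFs and
200 genes — sizes chosen so each end-to-end study takes seconds while
every stage operates in its intended regime (tens of modules, dozens of
OMUs). Recovery is checked on ten seeded 30-drug studies at GRmax noise
0.1 (requiring fitted |r| ≥ 0.6) and, for ranking, on fifty seeded
20-drug studies with three planted synergy pairs (requiring the planted
pairs' mean DGIS rank to beat the median in at least 90% of replicates).
Oracle equivalence tests compare the Jaccard, ILR, OLS, DGIS, Bliss/ZIP
and pooled-MLE computations against naive brute-force transcriptions on
a hundred randomized small instances each.

# Known limitations

* The OMU merge is a greedy single pass; it is deterministic and
  oracle-tested, but the extension/intersection rule is one defensible
  design among several — different deterministic merge orders would give
  different (equally valid) compendia.
* The differential-modularity definition is one of several that satisfy
  the stated contracts; it scores change against a block-rescaling null
  rather than re-deriving any particular published differential-network
  method exactly.
* The ZIP scorer uses fitted margins with the raw observed combination
  response; it is a documented implementation of the zero-interaction-
  potency idea, not a byte-level port of existing synergy software.
* Mean GRmax of widely shared OMUs shrinks toward zero by construction
  (each member contributes only its proportional share), so the balance
  tree's informative splits sit close to the centre of the GRmax axis.
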