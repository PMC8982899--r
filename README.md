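# omusynergy

Prioritize synergistic two-drug combinations from **single-drug** data.

Testing all pairwise drug combinations in dose–response matrix
experiments scales quadratically with the panel size. `omusynergy`
implements a network-based enrichment pipeline for researchers who have,
for each drug alone, (a) a transcriptomic profile of treated cells and
(b) a growth-rate-inhibition phenotype (GRmax ∈ [−1, 1]; negative =
cytotoxic, 0 = cytostatic, 1 = no effect). From these it ranks every
two-drug pair by predicted joint growth impact, so wet-lab validation can
focus on a short top list.

## The model

For each condition a weighted bipartite TF→gene regulatory network *W*
is inferred by message passing that integrates a regulatory prior, TF–TF
protein interactions and gene co-expression (continuous Tanimoto
messages, update step 0.1). Comparing each drug network with the
untreated network under the baseline community structure gives a
differential modularity matrix

&nbsp;&nbsp;&nbsp;&nbsp;*D* = max(0, *w*<sub>t</sub> − *w*<sub>c</sub> − *e*<sub>conf</sub>(ρ − 1)),

whose seeded Louvain communities are the drug's **differential gene
modules**. Similar modules across drugs (edge-set Jaccard
*J* = |A∩B| / |A∪B|) are pooled greedily into **operational module
units** (OMUs); each OMU carries its shared edge structure, member
modules, and a mean GRmax

&nbsp;&nbsp;&nbsp;&nbsp;mean GRmax = Σᵢ GRᵢ·Xᵢ / Σᵢ Yᵢ,

with Xᵢ the member-module weight and Yᵢ its sample's total module
weight. Each drug becomes a sparse vector over the OMU system, analysed
compositionally: at an internal node of the mean-GRmax hierarchy the
isometric log-ratio balance

&nbsp;&nbsp;&nbsp;&nbsp;*b* = √(n<sub>L</sub>n<sub>R</sub>/(n<sub>L</sub>+n<sub>R</sub>)) · ln( g(i<sub>L</sub>) / g(i<sub>R</sub>) )

is regressed on GRmax (node chosen to maximize |r| among candidates with
centroid in [−0.5, 0.5]). Pair vectors are the component-wise maximum of
the two single-drug vectors, renormalized; their model prediction is the
**growth impact score** (GIS), and the **differential growth impact
score** (DGIS) is the signed gap between a pair's GIS and the nearer of
its two self-pair GIS values (zero in between). Pairs are ranked by
ascending DGIS. Validation utilities score 6×6 dose–response matrices
with a ZIP delta model (synergy call at > 5 percentage points) and
quantify top-list enrichment with a two-trial maximum-likelihood
proportion.

## Worked example

```r
library(omusynergy)

st  <- simulate_study(study_config(n_drugs = 12, seed = 42))
run <- run_pipeline(st)

run$model
#> <omu_balance_fit> node N10: GRmax = -0.2734 -0.3233 * ILR (r = -0.911, R^2 = 0.829, n = 12)

head(dplyr::as_tibble(run$ranking)[, c("drug_1","drug_2","gis","dgis","rank")], 5)
#> # A tibble: 5 × 5
#>   drug_1 drug_2    gis  dgis  rank
#>   <chr>  <chr>   <dbl> <dbl> <int>
#> 1 drug03 drug10 -0.235 -1.08     1
#> 2 drug05 drug10 -0.223 -1.08     2
#> 3 drug10 drug12 -0.226 -1.05     3
#> 4 drug03 drug11 -0.204 -1.04     4
#> 5 drug05 drug11 -0.191 -1.03     5
```

The fitted balance explains 83% of the GRmax variance across the twelve
synthetic drugs (r = −0.911: drugs whose differential-module mass sits on
the low-mean-GRmax side of the balance kill cells). The ranking lists all
66 pairs by DGIS; the most negative values (here ≈ −1.08) are pairs whose
combined module vector is predicted to inhibit growth well beyond either
drug alone. `autoplot(run$model)`, `autoplot(run$ranking)` and
`plot_omu_vectors(run$vectors, run$system, st$gr)` draw the regression,
the DGIS distribution and the drug-by-OMU activity landscape.

Enrichment of a validated top list against a random draw (8 synergistic
of 30 top-ranked vs 2 of 160 random pairs from a 57-drug panel):

```r
joint_binomial_mle(8, 30, 2, 160, finite_population = n_pairs(57))
#> # A tibble: 2 × 4
#>   model           m_hat joint_prob_at_mhat k_hat
#>   <chr>           <dbl>              <dbl> <dbl>
#> 1 binomial       0.0526        0.000000721    NA
#> 2 hypergeometric 0.0520        0.000000442    83
```

Both models put the maximizing proportion of truly synergistic pairs at
≈ 0.052 — far above the 8/30 top-list hit rate a random 2/160 draw would
suggest, i.e. the ranking enriches real synergy.

A command-line front end wrapping these functions is installed at
`system.file("cli", "omu-synergy.R", package = "omusynergy")` with
`simulate`, `run`, `zip` and `enrich` subcommands.

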