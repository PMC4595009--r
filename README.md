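# binm — direct protein interaction scoring for AP-MS co-complex networks

Affinity purification–mass spectrometry (AP-MS) screens recover
**co-complex** relationships: a high-confidence score between two
proteins means they belong to a common complex, not that they physically
touch. Direct physical (binary) interactions are therefore obscured by
indirect associations between proteins that merely co-occur in
purifications. `binm` re-scores a weighted co-complex network from its
topology alone so that high scores indicate direct physical contact —
for anyone who needs the physical wiring inside complexes: interface
mapping, structural modelling, assembly analysis, binary-interactome
construction.

## The model

Write $W_{obs}$ for the symmetric matrix of observed co-complex scores
in $[0,1]$ (zero diagonal). The model assumes observed scores are the
sum of direct and indirect contributions, with indirect association
mediated by common neighbours of the direct network:

$$W_{obs} = W_{dir} + W_{indir}, \qquad
  \mathcal D(W_{indir}) = \mathcal D(W_{dir}^2),$$

where $\mathcal D$ zeroes the diagonal. The direct-interaction matrix is
estimated by the ridge-regularized Frobenius approximation

$$\min_{W_{dir}\ge 0}\;
  \bigl\|\mathcal D\!\left(W_{obs} - (W_{dir}+W_{dir}^2)\right)\bigr\|_F^2
  + \lambda\|W_{dir}\|_F^2,$$

solved by a multiplicative update that preserves nonnegativity,
symmetry and — crucially — the observed support: initialized at
$W_{dir}=W_{obs}$, an observed zero stays exactly zero, so the method
re-scores observed edges and never invents new ones. Observed edges
ranked by their fitted $w^{dir}_{ij}$ are the predicted direct
interactions; an F2-optimal rank cutoff against a reference set turns
the ranking into a binary interaction network.

The package also ships the full evaluation battery (AUC/ROC and top-k
curves against binary references, external structure-score enrichment,
complex-connectivity counts, genetic-profile reference sets, Jaccard
overlap, bait-prey score t-tests), a planted-complex synthetic
benchmark generator, readers/writers for all the plain-text formats
involved, and a command-line interface (`fit`, `evaluate`, `cutoff`,
`simulate`).

## Worked example

Simulate a planted benchmark (20 complexes, ground truth known), fit
the model, and evaluate the recovery:

```r
library(binm)

sim <- simulate_apms(weight_low = 0.2, weight_high = 0.4, seed = 42)
sim
#> <binm_sim> 20 complexes | 202 direct edges | 262 observed edges | noise_sd = 0.02 | seed = 42

fit <- fit_binm(sim$observed)   # lambda = 1 by default
fit
#> <binm_fit> 109 proteins, 262 edges | lambda = 1 | 11 iteration(s), converged | objective 28.3017

ranked <- rank_edges(fit)
head(ranked, 5)
#> # A tibble: 5 × 5
#>    rank protein_a protein_b binm_score obs_score
#>   <int> <chr>     <chr>          <dbl>     <dbl>
#> 1     1 P047      P049           0.343     0.840
#> 2     2 P106      P108           0.337     0.820
#> 3     3 P068      P072           0.335     0.791
#> 4     4 P010      P012           0.332     0.807
#> 5     5 P007      P010           0.326     0.792

edge_auc(ranked, sim$truth)                            # fitted ranking
#> [1] 0.9707921
edge_auc(ranked, sim$truth, score_col = "obs_score")   # raw scores
#> [1] 0.9480198

sel <- select_cutoff(ranked, sim$reference, step = 1)
sel
#> <binm_cutoff> selected cutoff 217 with F2 = 0.9756 (grid of 262 cutoffs)

net <- binary_network(ranked, sel$cutoff)
complex_connectivity(net, sim$complexes)
#> [1] 19
```

Reading the numbers: of 262 observed edges, 202 are planted direct
edges and 60 are pure common-neighbour artifacts. The fitted ranking
separates the two with AUC 0.971, above the 0.948 achieved by the raw
observed scores — the re-scoring sharpens the direct/indirect
distinction. The F2-maximizing cutoff (217) lands near the planted
direct-edge count (202), and the resulting binary network sufficiently
connects 19 of the 20 planted complexes. Note the fitted scores shrink
toward zero (ridge penalty with $\lambda = 1$); only their order
matters.

The same workflow from a shell:

```sh
binm simulate --n-complexes 20 --weight-low 0.2 --weight-high 0.4 --seed 42 --out sim/
binm fit --edges sim/observed_edges.tsv --out fit/
binm cutoff --ranked fit/ranked_edges.tsv --reference sim/reference_pairs.tsv --step 1 --out cut/
```

(the `binm` script is installed under `system.file("exec", "binm",
package = "binm")`).

Real networks enter through `read_weighted_edges(path, min_score,
scale)` — e.g. a bootstrap-scored edge list truncated at 0.1, or any
scored edge list min-max scaled onto $[0,1]$ — with reference pair
sets, complex catalogs and genetic-interaction profile matrices read by
`read_reference_pairs()`, `read_complexes()` and `read_profiles()`.

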