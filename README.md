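# pathmult

Shortest-path **multiplicity** analysis for complex networks.

The small-world effect says the shortest path between two nodes is
typically short. This package asks a complementary question: how *many*
shortest paths does a node pair have? That count — the pair's path
multiplicity, h<sub>ij</sub> — measures routing-choice diversity: a pair
with one geodesic poses no decision, a pair with dozens invites hesitation.
`pathmult` computes h<sub>ij</sub> for all pairs of an undirected network,
aggregates it, characterises its distribution, and benchmarks networks
against matched random-graph models and classical topology metrics. It is
aimed at network scientists working with connectomes, infrastructure,
social and web graphs at desk scale (up to a few thousand nodes).

## The quantities

For a simple connected undirected graph G with N nodes, adjacency matrix
A, geodesic lengths l<sub>ij</sub> and geodesic counts h<sub>ij</sub>
(h<sub>ii</sub> = 0):

- **per-node degree**  d̃<sub>i</sub> = (1/(N−1)) Σ<sub>j≠i</sub> h<sub>ij</sub>
- **network index**    Φ(G) = (1/N) Σ<sub>i</sub> d̃<sub>i</sub> = Σ<sub>i</sub>Σ<sub>j≠i</sub> h<sub>ij</sub> / (N(N−1)) ≥ 1,

with Φ = 1 exactly when every geodesic is unique (trees, stars, complete
graphs). The all-pairs counts come from a matrix-power sweep: walks of
length equal to the graph distance are exactly the geodesics, so masking
the already-resolved pairs and accumulating H ← H + T ⊙ A<sup>k</sup> for
k = 1, 2, … fills the count matrix in O(diameter · N³). An independent
per-source BFS that accumulates predecessor counts serves as a
verification oracle; the two must agree exactly.

The empirical distribution P(h) over unordered pairs (and likewise the
degree distribution P(d)) can be fitted with a full-range power law
p(x) = a·x<sup>−α</sup> by nonlinear least squares, with goodness of fit
R² = 1 − SS<sub>res</sub>/SS<sub>tot</sub>.

## Worked example

The 6-node graph formed by the union of four length-3 geodesics between
v1 and v6:

```r
library(pathmult)
g  <- make_fixture("fig1_union")
ph <- path_hesitation(g)
ph
#> Path multiplicity of a connected graph (N = 6, method = matrix)
#>   Path Hesitation Index  Phi = 1.7333
#>   diameter = 3, max pairwise count = 4
ph$H["v1", "v6"]   # 4 geodesics between v1 and v6 ...
#> [1] 4
ph$L["v1", "v6"]   # ... each of length 3
#> [1] 3
round(phd_vector(ph), 3)
#>  v1  v2  v3  v6  v5  v4
#> 2.0 1.6 1.6 2.0 1.6 1.6
pha_distribution(ph)
#> Empirical path-multiplicity distribution: 4 support values over 15 observations
#>  value count       prob
#>      1     8 0.53333333
#>      2     4 0.26666667
#>      3     2 0.13333333
#>      4     1 0.06666667
```

Of the 15 node pairs, 8 have a unique geodesic while the pair (v1, v6)
has 4 — averaging to Φ = 52/30 ≈ 1.733, a mildly "hesitant" toy network.

A model-comparison run — a clustered scale-free target versus a matched
Erdős–Rényi reference with the same size and density, plus a power-law fit
of the target's multiplicity distribution:

```r
target <- sample_cba(500, m = 3, ms = 1, seed = 42)
phi_index(path_hesitation(target))
#> 5.261
er <- matched_reference(target, "er", seed = 1)
phi_index(path_hesitation(er))
#> 3.991
fit_power_law(pha_distribution(path_hesitation(target)))
#> Power-law fit p(x) = a * x^(-alpha)  [linear space, full range]
#>   prefactor a = 0.316, exponent alpha = 1.149
#>   R^2 = 0.9775 on 105 support points
```

The matched random reference is markedly less hesitant than the clustered
target, and the target's count distribution is well described by a power
law — the directional pattern these tools are built to expose.

`global_metrics()`, `node_centralities()`, `top_k_overlap()` and
`metric_correlations()` supply the classical-metric side of the
comparison; `inst/cli/pha.R` wraps everything as shell subcommands
(`compute`, `fit`, `generate`, `match`, `report`, `fixture`).

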