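---
title: "Methods: counting geodesics and measuring path multiplicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counting geodesics and measuring path multiplicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmult)
```

## The model

`pathmult` works on simple, undirected, connected graphs. For every
unordered node pair $(i, j)$ it computes the geodesic length $l_{ij}$ and
the number of distinct geodesics $h_{ij}$, with $h_{ii} = 0$ by
definition and $h_{ij} \ge 1$ on a connected graph. Two aggregates
summarise the pairwise counts:

$$\tilde d_i = \frac{1}{N-1}\sum_{j \ne i} h_{ij}, \qquad
  \Phi(G) = \frac{1}{N}\sum_i \tilde d_i
          = \frac{\sum_i \sum_{j\ne i} h_{ij}}{N(N-1)} \ \ge\ 1 .$$

$\Phi = 1$ holds exactly when every pair's geodesic is unique — trees,
stars and complete graphs — and grows as routing alternatives multiply.
Disconnected input is always an error rather than a silently partial
answer; `giant_component()` is the supported preprocessing step, matching
the usual practice of analysing the giant connected component.

## The matrix-power algorithm

The engine behind `path_hesitation(..., method = "matrix")` rests on one
identity: the $(i,j)$ entry of $A^k$ counts walks of length $k$, and a
walk whose length equals the graph distance cannot revisit a node, so it
is a geodesic. Hence $h_{ij} = (A^{l_{ij}})_{ij}$. The sweep initialises
$H = L = 0$, $k = 1$, and repeats:

1. build the mask $T$ with $t_{ij} = 1$ exactly where $h_{ij} = 0$ for
   $i \ne j$;
2. accumulate $H \leftarrow H + T \odot A^k$ and stamp $L$ with $k$ on the
   newly filled entries;
3. advance $A^k \leftarrow A^{k-1} A$, $k \leftarrow k + 1$,

terminating when no off-diagonal zero remains. Each iteration costs one
dense $N \times N$ multiplication, so the sweep is
$O(\mathrm{diameter}\cdot N^3)$ — far below the $O(N^4)$ of running a
path search per pair.

Two details matter:

- **Diagonal masking.** A literal "mask wherever $h_{ij} = 0$" would
  eventually fill the diagonal too, because $A^k$ develops non-zero
  diagonal entries (closed walks) as $k$ grows. Since $h_{ii} = 0$ by
  definition, the mask excludes the diagonal permanently.
- **Termination bound.** A geodesic has at most $N - 1$ edges, so if
  off-diagonal zeros survive at $k = N - 1$ the graph is disconnected and
  the engine stops with an error pointing at `giant_component()`.

`method = "bfs"` is a fully independent implementation: one
breadth-first search per source accumulating predecessor counts along the
shortest-path DAG ($\sigma_w \mathrel{+}= \sigma_v$ whenever
$d_w = d_v + 1$), $O(N(N + W))$ overall. The test suite requires exact
equality of both $H$ and $L$ between the two engines on hundreds of
random graphs, plus agreement with closed forms (corner-to-corner
$\binom{a+b-2}{a-1}$ on an $a \times b$ grid, $n!$ for hypercube
antipodes, 2 for even-cycle antipodes) and with a third, brute-force path
enumeration on the toy examples.

### Exactness of the counts

Counts are held in doubles, which represent integers exactly up to
$2^{53}$. Before each matrix multiplication the engine checks the
conservative bound $N \cdot \max(A^k) < 2^{53}$ (each entry of the next
power is a sum of at most $N$ products with a 0/1 matrix) and stops with
an explicit error rather than returning a rounded count. Graphs at the
scale this package targets sit many orders of magnitude below the bound;
the guard exists so that the exactness contract can never fail silently.
The BFS engine's accumulators are the counts themselves, which are always
no larger than the largest entry of $H$.

## Power-law fitting

`fit_power_law()` fits $p(x) = a\,x^{-\alpha}$ to an empirical
distribution over its **full observed support** — no binning, no lower
cut-off, no tail truncation — by Levenberg–Marquardt nonlinear least
squares in linear probability space. The goodness of fit is
$R^2 = 1 - SS_{res}/SS_{tot}$ evaluated on the same linear-space values
the fit minimised. Design choices, all genuinely open and therefore
fixed here as package policy:

- **Linear space by default.** Least squares on $p(x)$ itself weights the
  (well-populated) head of the distribution most; `log_space = TRUE`
  switches to log–log regression, which weights the tail, and then also
  reports $R^2$ in log space for internal consistency. The two can
  disagree substantially on noisy tails; comparisons should pick one and
  stay with it.
- **Initialisation.** The exponent starts from the log–log regression
  slope and the prefactor from its intercept — deterministic and
  scale-free. If that starting point already fits with (numerically) zero
  residual, as on noise-free power-law or constant data, it is returned
  directly: iterating from a zero-residual point is ill-posed.
- **Convergence.** Residual-norm tolerance $10^{-10}$, at most 1000
  iterations; non-convergence is an error reporting the starting values,
  never a silent best-effort result.
- **Degenerate inputs.** Fewer than 3 distinct support values is an
  under-determined fit and an error. A constant distribution fits with
  $\alpha \approx 0$ but has $SS_{tot} = 0$, so its $R^2$ is reported as
  `NA` rather than a misleading number.

This is deliberately *not* a maximum-likelihood tail estimator with
$x_{min}$ selection (Clauset-style); full-range least squares is the
convention the rest of the package's comparisons assume, and the two
approaches answer different questions.

## Reference models

Four generators support the model comparisons, all emitting simple
undirected graphs on exactly $n$ nodes and reproducible from a seed:

- **ER** — each pair an edge independently with probability $p$.
- **NW** — circular lattice, `k_ring` neighbours per side (default 2,
  base degree 4), plus one candidate random shortcut per lattice edge with
  probability `p_tilde`; shortcut **addition**, no rewiring. The
  Newman–Watts construction is used even where the comparison literature
  loosely calls the parameter a "rewiring probability": addition is the
  construction the cited small-world variant actually defines, and it
  keeps the graph connected.
- **BA** — growth from a complete seed clique on `m0` nodes (the seed
  topology is not pinned down in the literature; a clique is the least
  arbitrary choice that makes degrees well-defined from the start), each
  arriving node attaching `m` edges to distinct targets drawn without
  replacement proportionally to degree.
- **CBA** — BA plus triad formation: after each preferential attachment
  to a target, `ms` further edges connect the newcomer to randomly chosen
  neighbours of that target, raising clustering; when fewer eligible
  neighbours remain the newcomer connects to all of them (saturation),
  so the parameter grid never dead-ends.

`matched_reference()` reproduces the "same size, similar density" design:
ER takes $p$ equal to the target's edge density (expected edge count then
equals the target's exactly); BA rounds $m = W/N$; NW takes
$k_{ring} = \lfloor W/N \rfloor$ and lets the shortcut probability absorb
the remainder, erroring when the target is sparser than a bare ring; CBA
accounts for its triad edges and rounds $m = W/(N(1+m_s))$ — the naive
$W/N$ rule would overshoot the target density by a factor $1 + m_s$.
Sparse ER/NW draws can be disconnected; they are re-drawn up to 100 times
and the giant component of the last draw is returned so $\Phi$ is always
defined.

### What the synthetic ensembles do and do not show

The generators emulate the *structural mechanisms* (randomness, shortcuts,
preferential attachment, triadic closure) at sizes of a few hundred to a
few thousand nodes — large enough for the directional phenomena to be
stable, small enough for exact all-pairs counting in seconds. The test
ensembles confirm the directional claim that matched ER and NW references
are less hesitant than a clustered scale-free target (checked at
$N = 500$ over 20 seeds), and that triad formation raises clustering.
They do **not** reproduce empirical magnitudes from real corpora: real
networks' community structure, degree correlations and sheer size are
outside what these toy mechanisms generate, so a passing suite says the
machinery is correct and the directions hold at desk scale — not that any
particular real network will show a specific $\Phi$.

## Classical metrics

`global_metrics()` reports size, mean degree, edge density, degree
assortativity (Pearson correlation of degrees across edge endpoints),
clustering, average geodesic length (reused from the same all-pairs pass
that produced $H$, and cross-checked against an independent BFS), and
$\Phi$. Two conventions are configurable because the comparison
literature leaves them open; the defaults are the scatter-plot
conventions: **mean local clustering** (degree-<2 nodes contributing 0)
with `clustering = "global"` for transitivity, and **Pearson**
cross-network correlations with `method = "spearman"` as the alternative.
Correlation against a constant column is reported as `NA`, not an error,
so tree-heavy ensembles (where the $\tilde d$ column is constant 1) pass
through cleanly.

`node_centralities()` aligns degree centrality $d_i/(N-1)$, betweenness
(normalised by $(N-1)(N-2)/2$), and $\tilde d_i$.
`betweenness_from_pha()` rebuilds betweenness *directly from $H$ and
$L$* — node $v$ lies on an $s$–$t$ geodesic iff
$L_{sv} + L_{vt} = L_{st}$, contributing $H_{sv}H_{vt}/H_{st}$ — and the
suite requires agreement with the standard accumulation algorithm, a
strong joint consistency check on both matrices. `top_k_overlap()` breaks
ranking ties by node index so overlap fractions are reproducible.

## Numerical and testing choices

- Problem sizes: engine-equivalence ensembles use 200 graphs of up to 60
  nodes; the floor property uses 200 ER(30, 0.15) draws; model-direction
  checks use $N = 500$ with 20 seeds — sizes chosen so exact all-pairs
  counting stays comfortable on a single core while leaving the tested
  phenomena well away from small-size noise.
- All stochastic tests and scripts run under fixed seeds; generators take
  an explicit `seed` argument and reproduce edge sets bit-identically.
- $\Phi$ and $\tilde d$ are exact ratios of integer sums and are stored at
  full double precision; rounding (e.g. to 4 decimals) happens only at
  presentation time.

## Limitations

- Directed, weighted, bipartite and temporal graphs are out of scope, as
  is enumerating the geodesics themselves (only counts and lengths).
- Dense $N \times N$ matrices bound practical size to a few thousand
  nodes; the package targets desk-scale analysis, not web-scale graphs.
- The power-law fit is descriptive (least-squares, full range), not a
  hypothesis test for power-law behaviour.
- Model matching targets edge density only; degree-preserving or
  clustering-preserving null models are deliberately not provided.
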