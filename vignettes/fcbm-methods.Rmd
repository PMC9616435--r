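---
title: "Fitness-corrected block models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitness-corrected block models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The package generates simple undirected graphs from the maximum-entropy
ensemble in which two families of statistics are constrained *on
average*: the number of links between every pair of blocks, and the
degree of every vertex. A block is a set of vertices sharing discrete
attributes; in the spatial application a block is a residence tile
crossed with an age group. Throughout the package, intra-block link
counts (and the corresponding pair counts $N_{II} = N_I(N_I-1)$) are
stored *doubled*, i.e. as ordered pairs — the single convention that
makes all row/column sums work out without special-casing the diagonal.

In degree-corrected mode the targets $K_{IJ}$ (expected block-pair link
counts) and $k_i$ (expected degrees) are supplied directly, typically
read off an observed graph that is to be randomized
(`constraints_from_graph()`). Internal consistency requires
$\sum_J K_{IJ} = \sum_{i \in I} k_i$ for every block.

In fitness-corrected mode the targets are *derived* from three
interpretable parameters (`build_constraints()`):

* a density $p \in (0,1)$;
* a symmetric mixing-density matrix $\Delta$ with ordered-pair sum 2,
  fixing the relative link density of every block pair;
* a positive fitness vector $f$, fixing the within-block heterogeneity:

$$K_{IJ} = p\binom{N}{2}\Delta_{IJ}, \qquad
  k_i = p\binom{N}{2}\frac{f_i}{\sum_{u\in I_i}f_u}\sum_J \Delta_{I_i J}.$$

These are consistent for *any* admissible $(p, \Delta, f)$, and because
$\sum_{IJ}\Delta_{IJ}=2$ the expected mean degree is exactly $p(N-1)$
(`density_from_mean_degree()` inverts this relation). Only fitness
*ratios* within a block matter; rescaling $f$ changes nothing.

Entropy maximization under these soft constraints factorizes the graph
probability into independent Bernoulli edges

$$p_{ij} = \frac{x_i x_j y_{I_iJ_j}}{1 + x_i x_j y_{I_iJ_j}},$$

with one positive multiplier $x_i$ per vertex and $y_{IJ}$ per block
pair — exponentiated Lagrange multipliers of the two constraint
families.

## Feasibility

The expectation constraints are unsatisfiable by any distribution over
simple graphs if some $k_i > N-1$ or some $K_{IJ} > N_{IJ}$, so
`constraint_set()` rejects such inputs outright (an error, not a
warning). Saturation is also treated as a practical boundary: targets
*at* the capacity force $p_{ij} = 1$, which no finite multiplier
reaches, and targets close to it make the solver slow (see below). The
same applies to subtler boundaries: degree sequences at an
Erdős–Gallai-type bound force deterministic edges and admit no interior
solution; the solver reports non-convergence rather than failing
silently.

## The exact solver

The multipliers solve a nonlinear system with $N + n(n+1)/2$ unknowns.
The package uses a damped multiplicative fixed-point iteration,

$$x_i \leftarrow x_i\,\frac{k_i}{\sum_{j\ne i} p_{ij}}, \qquad
  y_{IJ} \leftarrow y_{IJ}\,\frac{K_{IJ}}{\sum_{i\in I,\,j\in J,\,i\ne j} p_{ij}},$$

alternating the two half-steps and recomputing probabilities in
between. This scheme is standard for maximum-entropy graph ensembles
(it is the likelihood-equation fixed point), is memory-light, and is
started from the sparse closed form below, which is exact in the
$p \to 0$ limit — at benchmark densities it typically converges in
tens of iterations. Safeguards:

* **Convergence criterion**: maximum constraint residual, normalized
  relatively for targets larger than one; default `tol = 1e-8`,
  `max_iter = 10000`.
* **Adaptive damping**: if the residual has not improved over a
  50-iteration window the update exponent is halved (down to 0.2),
  which settles oscillatory cases.
* **Degenerate targets**: $k_i = 0$ pins $x_i = 0$; $K_{IJ} = 0$ pins
  $y_{IJ} = 0$; both are excluded from iteration (they are the limits
  of the system).
* **Determinism**: the iteration itself uses no randomness. The `seed`
  argument is consumed only if the deterministic pass fails, in which
  case one multiplicatively perturbed restart is attempted and the
  report records it.
* **Gauge fixing**: $(x, y) \mapsto (c_I x_i,\, y_{IJ}/c_Ic_J)$ leaves
  every $p_{ij}$ unchanged, so after convergence the solution is
  rescaled so that $\sum_{i\in I} x_i = \sum_{i\in I} k_i$ per block,
  making multiplier outputs comparable across runs.

Near-saturated configurations (block-pair targets at a large fraction
of capacity combined with a dominant-fitness vertex) converge slowly or
not at all; the `SolverReport` carries the residual so callers can
decide. The benchmark configurations are far from this regime.

## Sparse closed forms

For $p \ll 1$ the logistic linearizes, $p_{ij} \approx x_i x_j y_{IJ}$,
and the system has the closed-form solution $x_i = k_i$,
$y_{IJ} = K_{IJ} / (\sum_{i\in I}k_i)(\sum_{j\in J}k_j)$
(`sparse_fcbm()`, `sparse_dcbm()`). Two numerical notes, both
documented consequences of adopting the closed form exactly as it is
usually written:

* the denominators use *full* block degree totals, dropping the
  $j \ne i$ self-exclusion of the underlying sums. This leaves an
  $O(1/N_I)$ relative error that does **not** vanish as $p \to 0$: with
  uniform fitness the exact intra-block probability is
  $K_{II}/N_I(N_I-1)$ while the closed form gives $K_{II}/N_I^2$, a
  constant floor of $1/N_I$. With heterogeneous fitness the
  linearization error dominates at moderate $p$ and the sparse-exact
  deviation does shrink monotonically as $p$ decreases — the regime the
  package tests.
* products $x_i x_j y_{IJ}$ can exceed 1 under heavy-tailed fitness;
  emitted probabilities are clipped at 1 and the number of clipped
  pairs is counted (`clipped_pairs()`) as a diagnostic of sparse-regime
  violation. Clipping (and the self-pair term) makes the realized mean
  degree of sparse-sampled benchmarks undershoot the target by roughly
  1–2% at $N = 10^4$.

## Degree-distribution estimators

With i.i.d. fitness from a density $p_f$ with mean $\langle f\rangle$,
inverting $k(f, I) \approx f\mu_I/\langle f\rangle$ (where
$\mu_I = \sum_J K_{IJ}/N_I$ is the expected mean degree of block $I$)
gives two estimators of the degree density: the block-resolved mixture

$$p_k(k) \approx \frac{\langle f\rangle}{N}\sum_I
  p_f\!\Big(k\frac{\langle f\rangle}{\mu_I}\Big)\frac{N_I}{\mu_I}$$

and the single-scale global form
$p_k(k) \approx p_f(k\langle f\rangle/\mu)\,\langle f\rangle/\mu$ with
$\mu$ the network mean degree. Both are exact changes of variables of
$p_f$, so the degree distribution inherits the fitness shape: Pareto
fitness with shape $a$ gives a $k^{-(a+1)}$ tail, lognormal fitness a
lognormal with the location shifted by $\log(\mu/\langle f\rangle)$,
and exponential fitness collapses the global form to $e^{-k/\mu}/\mu$
for *any* rate. Blocks with $\mu_I = 0$ contribute a point mass
$N_I/N$ at $k = 0$, the limit of the change of variables.

Empirical degrees are integers while the estimators are continuous, so
for comparison the densities are evaluated at integer $k$ and
renormalized over the integer grid (this mirrors overlaying analytic
curves on degree histograms); `ks_distance()` then reports the sup
difference of the two CDFs, optionally restricted to $k \ge 1$ because
the estimators are least reliable at very small degrees.

Two validity conditions, stated by the derivation itself, matter in
practice and bound what agreement one should expect:

* the inversion uses $\sum_{u\in I}f_u \approx N_I\langle f\rangle$,
  so blocks must be **well populated**. With mean occupancy below ~10
  the within-block share normalization visibly shrinks the upper tail
  (a vertex's large fitness inflates its own denominator) and the
  occupancy noise in $\mu_I \propto 1/N_I$ spreads the block-resolved
  mixture, adding a few hundredths to its KS distance;
* the estimators describe *expected* degrees; sampled degrees carry
  binomial noise of scale $\sqrt{\mu}$. For fitness families with a
  hard lower support edge (Pareto), this noise smooths the estimator's
  sharp cutoff at $k = \mu_I x_m/\langle f\rangle$ and keeps the KS
  distance near 0.05 even when everything else is exact.

The estimator-accuracy test therefore exercises large-block
configurations, where the block-resolved form is at least as accurate
as the global one; the stylized-city acceptance checks run the exact
benchmark geometry at both scales and inherit these limits, which is
visible in their results at reduced population.

## The data-driven spatial construction

`build_city()` assembles the benchmark end to end:

1. **Tessellation** (`tessellate_disk()`): a square lattice of pitch
   $l$ whose cell corners sit on multiples of $l$ (the disk center is a
   lattice corner); tiles are kept when their center is inside the
   disk. A 2.5 km disk with $l = 0.5$ km gives 80 tiles.
2. **Distances** (`tile_distance_matrix()`): Euclidean center-to-center
   distances normalized by $l/2$, with $d_{II} = 1$ — same-tile pairs
   sit at half the distance of adjacent-tile pairs ($d = 2$). Euclidean
   (rather than road) distance is used; the stylized disk has no road
   network. Tile centers represent the tiles.
3. **Social mixing** (`mixing_matrix_from_contacts()`): a raw,
   generally asymmetric age-contact matrix is symmetrized by
   reciprocity of total contact volumes,
   $\tilde s_{IJ} = (c_{IJ}w_I + c_{JI}w_J)/2$, and normalized so the
   unordered-pair sum is 1. Any positive scale would be absorbed by the
   next step; the unit normalization just standardizes reported
   matrices.
4. **Mixing densities** (`build_delta()`): gravity weights
   $w_{IJ} = d_{IJ}^{-\beta} s_{IJ}$ per unordered block pair,
   normalized over unordered pairs, emitted with the doubled diagonal
   ($\Delta_{II} = 2w_{II}$) so the ordered sum is exactly 2. This is
   the unique convention compatible with doubled intra-block counts: a
   single block reduces to $\Delta = [2]$, i.e. an Erdős–Rényi graph
   with expected $p\binom{N}{2}$ edges.
5. **Population** (`sample_population()`): tiles drawn with probability
   proportional to a density evaluated at tile centers — uniform,
   $1 + r/R$ (increasing) or $2 - r/R$ (decreasing), the simplest
   monotone families — and ages i.i.d. from the age fractions.
6. **Blocks**: occupied tile-by-age cells. Empty cells are dropped
   *before* $\Delta$ is built (block fitness totals would otherwise be
   undefined) and the normalization runs over surviving blocks only.
7. **Capacity adjustment**: with a finite population some tiny blocks
   (size 1–3) receive $\Delta$ weights whose implied $K_{IJ}$ exceeds
   the hard pair capacity $N_{IJ}$ — most visibly singleton blocks,
   whose intra-pair capacity is zero. The weight of any such pair is
   zeroed and $\Delta$ renormalized, repeating until every target is
   attainable. The removed unordered weight is reported
   (`dropped_weight`; well under 1% at benchmark scales and zero for
   most seeds at $N = 10^4$) and the affected vertices keep all their
   cross-block connectivity.
8. **Fitness and constraints**: fitness is drawn i.i.d. from the chosen
   family, $p$ is set to $\mu/(N-1)$, and the strict constraint set is
   assembled.

Defaults mirror the benchmark: $N = 10^4$ inhabitants, 2.5 km disk,
0.5 km tiles, $\beta = 1$, target mean degree $\mu = 25$, and a 3×3
grid of spatial densities (uniform / radially increasing / radially
decreasing) by fitness families (Pareto / lognormal / exponential),
`stylized_city_configs()`. The synthetic age pyramid uses five groups
with fractions (0.15, 0.20, 0.25, 0.25, 0.15), and the synthetic
contact matrix is banded-assortative with strict row-wise diagonal
dominance and mild asymmetric noise — explicit stand-ins for
census/survey inputs, configurable and deliberately simple. Fitness
defaults are Pareto(2.5, 1), lognormal(0, 1), exponential(1); by the
change-of-variables property the degree *shape* depends on the family
only through its shape parameter, so scale/rate choices are
inconsequential.

What the generator deliberately does not emulate: real road-network
distances, household and workplace structure, empirically calibrated
age bands, spatially correlated fitness, or degree correlations beyond
those induced by blocks and fitness. Passing benchmarks on the
stylized city therefore validates the machinery (constraints, solver,
closed forms, estimators, sampling), not the sociological fidelity of
any particular real-world network.

## Randomness and reproducibility

Every stochastic stage takes an explicit integer seed. A configuration
or ensemble root seed spawns per-stage / per-graph sub-seeds
deterministically (recorded in ensemble attributes and run manifests),
so a pipeline run can be reproduced exactly from its manifest. Vertex
and block indices are 1-based in memory (idiomatic R) and 0-based in
all CSV/GraphML artifacts, the interchange convention used by the
readers and writers.

## Problem sizes used in the checks

The test suite solves exact models up to $N = 500$ (and $N = 60$ for
the sparse-limit comparison), enumerates all graphs exhaustively up to
$N = 6$, uses 20,000-draw Monte-Carlo oracles on 6-vertex models, and
samples ten-graph ensembles of the full $N = 10^4$ stylized city plus
the nine-configuration grid at $N = 3{,}000$. These sizes were chosen
so that every distributional check retains standard errors well below
the tolerances it asserts.
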