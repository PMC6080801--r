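---
title: "Modeling the formation and remodeling of ductal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the formation and remodeling of ductal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ductnet)
```

## The system and the question

The embryonic pancreas builds its duct system in two acts. Early on,
isolated microlumens nucleate in the stratified epithelium and connect to
their neighbors, producing a dense, loop-rich mesh of ducts — a *plexus* —
that is roughly planar and has no hierarchy. Later this plexus remodels:
redundant connections disappear, and what remains is a tree draining
through a single exit into the duodenum. `ductnet` implements a
quantitative pipeline for this process: statistics that characterize a
digitized duct skeleton at any stage, a stochastic growth model that
reproduces the plexus, a flux-based pruning model that turns a plexus
into a tree, and the shear-stress law by which duct diameters adapt to
the flow they carry.

The common substrate is the `spatial_network`: nodes with 3D positions
(terminal ends and duct intersections of a skeletonized network), edges
with positive lengths (stored lengths win over straight-line distances,
because real ducts curve), and one designated root — the exit node.
Degree-2 nodes are contractible bookkeeping (`contract_degree2()`), since
they merely mark the continuation of a duct; contraction preserves total
length and the cycle-space dimension exactly.

## Network statistics

`summarize_network()` produces the per-sample statistic vector:

* **Polygon counts** `count_polygons()`: simple cycles of length 3–5 from
  traces of adjacency powers, with degeneracy corrections
  (tr A³⁄6; squares and pentagons with walk corrections involving
  choose(dᵢ, 2) and A³ᵢᵢ). The square-count correction term is the
  binomial coefficient choose(dᵢ, 2): on a 4-cycle this reading gives
  exactly one square, whereas a dᵢ² reading would go negative. The
  formulas are validated in the test suite against exhaustive cycle
  enumeration on dozens of random graphs.
* **Cost** `network_cost()`: total duct length over the length of the
  Euclidean minimum spanning tree on the same nodes — at least 1, with
  the excess measuring redundancy.
* **Performance** `network_performance()`: mean shortest-path distance
  over all ordered node pairs (self-pairs included, 1/N² normalization,
  following the defining formula literally) divided by the same mean on
  the MST. Below 1 means redundant links shorten transport.
* **Exit centering** `mean_distances()`: ⟨D_root⟩, ⟨D⟩, and their ratio.
  As a network reorganizes around its exit the ratio falls toward the
  value of a tree centered on the root.
* **Dimension** `network_dimension()` (below).

Group contrasts use classic pooled two-sample, two-tailed t tests
(`compare_groups()`), with a Bonferroni-adjusted threshold alpha/m over
the m measures tested; SEMs accompany every mean. Degree-preserving
double-edge-swap randomization (`randomize_degree_preserving()`, default
10·E attempted swaps, ensembles of 100) provides the null networks
against which the digitized structures are compared: a swap is rejected
if it would create a self-loop or multi-edge or disconnect the network,
so the degree multiset and connectivity are invariant by construction.

### The dimension estimator

For each sampled node, nodes are ranked by weighted network distance and
a line is fitted to log(cumulative count) against log(radius); the
dimension is the mean slope (all nodes when N ≤ 500, else a seeded
500-node subsample). Two numerical choices matter:

* **Fit window.** Radii where the cumulative count lies between 5 and
  N/2, excluding both small-count noise near the seed node and
  saturation at the network boundary. Both bounds are configurable.
* **Shell centering.** On networks whose distances take few distinct
  values (unit-spacing lattices), a radius r stands for a whole shell of
  nodes. Fitting raw ranks against raw radii then underestimates the
  slope badly — on a 20×20 grid the estimate sinks to ~1.7 even though
  the lattice limit is 2, because every shell enters at its upper edge
  on both axes. The estimator therefore fits shell-midpoint counts
  against shell-centered radii (r + h/2, where h is the median spacing
  of distinct radii). On continuous distance spectra h is negligible and
  the correction vanishes; on the calibration references it recovers
  0.98 on a 200-node chain and 1.95 on a 20×20 grid.

Finite patches remain boundary-limited: a 100-node triangular-lattice
mesh measures ~1.7, approaching 2 only as the patch grows. Estimates on
small networks should be read as lower bounds on the planar value.

## The growth model

New lumen nodes appear and connect with noise. One iteration:

1. Propose a point uniformly in the ball of radius `max(d_com) + 0.5`
   around the nodes' center of mass; accept with probability
   ∏ᵢ(1 − exp(−dᵢ)), dᵢ the distances to existing nodes. The kernel
   vetoes proposals on top of existing lumens and saturates quickly —
   it also sets the length unit (about one inter-lumen spacing).
2. Draw M ~ Poisson(λ) and link the new node to M + 1 distinct targets
   chosen uniformly from its M + 1 + Δ nearest nodes (both counts capped
   at the current network size). λ controls how much redundant linking
   happens; Δ controls how spatially specific it is.
3. Repeat until the target size is reached.

The published acceptance expression carries a sign typo (∏(1 − exp(dᵢ))
is negative for d > 0); the implementation uses the only reading that is
a probability and penalizes proximity. Growth is in 3D — the simulated
plexus is roughly spherical, which is also why its measured dimension
(~2.7) exceeds the planar in vivo value; the model deliberately has no
growth direction or mesenchymal guidance. Defaults are the plexus best
fit: λ = 0.25, Δ = 1, 320 nodes, started from two nodes a unit apart
(a single-node start would leave the first attachment undefined).
An alternative initialization (`init = "l_system"`) seeds growth with a
random dichotomic tree — fixed unit branch lengths in uniformly random
directions — to emulate stereotyped early branching; its loop-suppressing
effect only becomes visible when the initial tree is a large fraction of
the final network.

All randomness flows through one seeded generator in a fixed order
(placement draws, then the Poisson draw, then the pool sample), so a
(parameters, seed) pair reproduces a network bit for bit.

```{r}
px <- make_plexus(seed = 1)
summarize_network(px, dimension = FALSE)[, c("n_nodes", "mean_degree",
                                             "n_triangles", "cost",
                                             "performance", "root_ratio")]
```

## Flux-based pruning

Fluid enters the plexus and leaves through the exit; ducts that carry
the least flow are eliminated first. Concentration φ diffuses along
links under the combinatorial Laplacian L = D − A — deliberately
unweighted, as in the source procedure, so duct lengths do not modulate
conductance (a conductance-weighted variant is out of scope). Boundary
handling is Dirichlet clamping: terminals (degree-1 nodes other than the
root) are held at φ = 1 and the root at φ = 0 after every forward-Euler
step `φ ← φ − C L φ Δt`. A second source mode (`all_nodes`) injects a
unit of fluid per step at every non-root node — ductal secretion
everywhere — and clamps only the root; only relative fluxes matter for
pruning, so its arbitrary scale is irrelevant. The production solver is
the direct sparse solve of the clamped linear system; the Euler
iteration is kept and cross-checked against it (≤ 1e−8) on every test
fixture. Defaults: C = 1, Δt = 1/(2·max degree + 1) (inside the
stability bound), stopping when the summed absolute per-step change
falls below 1e−10·N.

Pruning then repeats: re-solve the steady state, remove the
lowest-|flux| link among the *redundant* links (non-bridges — removal
must not fragment the network), one link per re-solve, until a spanning
tree remains. Equal fluxes are broken lexicographically by sorted
node-ID pair, so runs are deterministic. Each removal is logged with its
flux and its distance to the root (from the removed link's closer
endpoint, on the pre-removal network). The random baseline
(`prune_random()`) removes uniformly chosen redundant links instead.

Two ensemble-level signatures distinguish the mechanisms, and both are
checked at n = 100 in the acceptance tests: flux-pruned trees have a
lower ⟨D_root⟩/⟨D⟩ than random-pruned trees (they prioritize the exit),
and the pruning trace's distance-to-exit falls with event index
(median Spearman ρ ≈ −0.7: remodeling sweeps from the periphery toward
the outlet).

```{r}
out <- prune_by_flux(make_plexus(n_nodes = 120, seed = 7))
c(edges = n_edges(out$tree), removals = nrow(out$trace),
  spearman = round(cor(out$trace$event, out$trace$dist_to_root,
                       method = "spearman"), 2))
```

## Diameter adaptation

Each duct's wall shear stress τ relaxes toward a common target:
∂d/∂t = K[τ(t) − τ_desired]·d, with τ = 32ηQ/(πd³) from Poiseuille flow.
The fixed point is d = (32ηQ/(πτ_desired))^{1/3} — diameter proportional
to the cube root of the flux — and `simulate_adaptation_ode()` verifies
convergence to it from any positive start (explicit Euler; the step must
keep 3·K·τ_desired·Δt well below 2, and a diameter crossing zero aborts
with a pointer to a smaller step). For two equal-length ducts in
parallel sharing a fixed total flow (flow split ∝ d⁴), the symmetric
state is unstable: one duct vanishes while the other attains the
steady diameter for the whole flow — the mechanism that lets redundant
ducts die (`simulate_parallel_ducts()`).

On a pruned tree the steady flow through a duct under uniform secretion
is exactly its *drained basin* — the number of nodes upstream
(`drained_basin()`, which also accumulates upstream duct length) — so
the adaptation analysis links to the pruned trees without re-solving
diffusion. `fit_powerlaw()` fits log(basin) against log(diameter) by
ordinary least squares (no errors-in-variables correction, matching the
original analysis); with diameters from the steady law plus 5%
multiplicative noise the recovered exponent is 3 within ±0.1 on a
320-node tree, against the laminar prediction of 3.

```{r}
tr <- out$tree
basin <- drained_basin(tr)
d <- steady_diameter(basin$basin_nodes, adaptation_params())
fit_powerlaw(basin$basin_nodes, d * exp(rnorm(nrow(basin), 0, 0.05)))[
  c("exponent", "r_squared")]
```

## Synthetic data: what it does and does not show

No public digitized duct networks exist, so every input is generated:

* `make_fixtures()` — exact small graphs (cycles, K4, chains, stars,
  balanced trees) whose statistics are hand-checkable; these anchor the
  unit tests.
* `make_lattice_mesh()` — a jittered, dilution-thinned triangular patch:
  planar and loop-rich like a plexus but *independent of the growth
  model*, so metric tests on it are not circular.
* `make_plexus()` / `make_tree()` — the growth model at its best fit
  (λ = 0.25, Δ = 1, N = 320, the published operating point) and its
  flux-pruned counterpart.
* `emit_sample_set()` — writes any collection as nodes/edges CSV pairs
  (`id,x,y,z` / `source,target,length`) plus a manifest; these
  round-trip exactly through `read_network()`, which is also the entry
  point for real digitized tables.

The generators emulate the *statistical* structure of the embryonic
duct system — size (~320 nodes), mean degree ~2.5, short loops, a rooted
exit, planarity for the mesh — not its anatomy. Passing tests therefore
demonstrate that the algorithms measure and transform such networks
correctly, not that the biological parameter values are recovered from
images; analyses of real samples should enter through
`read_network()` and will inherit every downstream step unchanged.

## Problem sizes and reproducibility

Simulation sizes used throughout the scripts and tests are chosen to
make ensembles cheap while keeping the statistics stable: networks of
50–320 nodes, ensembles of 10–100, 10⁴ draws for attachment statistics.
Every stochastic step takes an explicit seed, and generator outputs are
bit-reproducible from (parameters, seed). The numbered scripts under
`analysis/` run the full pipeline in order and write their tables under
`results/`; `scripts/acceptance.R` recomputes the headline quantities
from scratch for any seed.

## Known limitations

* Growth is isotropic and 3D; real plexus growth is guided and nearly
  planar, so simulated dimensions overshoot the in vivo value.
* Diffusion uses unit conductances; duct length and caliber do not
  feed back into the flux used for pruning (adaptation is analyzed at
  steady state, downstream of pruning).
* The dimension estimator is boundary-limited on small patches (see
  above).
* Polygon counting stops at pentagons, as in the defining analysis;
  longer loops are invisible to it.
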