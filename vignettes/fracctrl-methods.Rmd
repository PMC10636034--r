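---
title: "Controlling long-memory dynamical networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling long-memory dynamical networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracctrl)
```

## The model and its assumptions

`fracctrl` works with discrete-time fractional-order dynamical networks

$$\Delta^{\alpha} x[k+1] = A\,x[k] + B\,u[k],$$

where the Grünwald–Letnikov fractional difference of order $\alpha_i$
expands the left-hand side into a convolution over the full state history
with kernel $\Psi(\alpha_i, j) = \Gamma(j-\alpha_i)/(\Gamma(-\alpha_i)\,
\Gamma(j+1))$. Equivalently,

$$x[k+1] = \sum_{j=0}^{k} A_j\, x[k-j] + B\,u[k], \qquad
A_0 = A - D(\alpha, 1),\quad A_j = -D(\alpha, j+1)\ (j \ge 1),$$

with $D(\alpha, j) = \mathrm{diag}(\Psi(\alpha_i, j))$. Two facts shape
everything downstream:

* for non-integer $\alpha_i \in (0, 1)$ the kernel never vanishes and
  decays like $j^{-(1+\alpha_i)}$ — *long-term power-law memory*;
* $\Psi(\alpha_i, 1) = -\alpha_i$, so $A_0 = A + \mathrm{diag}(\alpha)$:
  the memory endows every node with a free *nodal* (self-loop) term even
  when $A$ has a zero diagonal.

Inputs are *dedicated*: $B$ is diagonal, and a node with a nonzero diagonal
entry is a **driven node**. The question is the minimum number (and
placement) of driven nodes so that the network is controllable within a
**time-to-control** $T$, i.e. any state is reachable in $T$ steps. We treat
the *structural* version: only the zero pattern of $A$ is known, and a
property holds if it holds for some (equivalently, almost every) numeric
realization of the free parameters.

The analysis sweeps $T \in \{1, \dots, N\}$. $T = 1$ forces every node to
be driven; by Cayley–Hamilton, whatever is controllable at all is
controllable by $T = N$, so larger horizons are only exposed in the
simulator and reachability computations, not in the selection sweep.

## Generic rank via the time-expanded graph

Structural controllability in $T$ steps is the statement
$\text{g-rank}\, [\,\bar B,\ \bar A\bar B,\ \dots,\ \bar A^{T-1}\bar B\,]
= N$. Powers of a structural matrix share parameters across entries, so the
generic rank of this block matrix is *not* the rank of a pattern with
independent entries; the correct semantics is combinatorial. We build the
**time-expanded graph**: state copies $(v, t)$ for layers $t$, arcs
$(v, t) \to (w, t+1)$ for every pattern arc $v \to w$, and one injection
vertex per driven node and injection time feeding $(i, k+1)$. The generic
rank equals the maximum number of vertex-disjoint paths from injections to
distinct final-layer copies, computed as unit-capacity max flow with node
splitting (a Dinic implementation in C++; deterministic, no randomness).
Certificates — the disjoint path family — are available on demand.

This graph computation is guarded by an independent *numeric* oracle:
`generic_rank_numeric()` draws random realizations (entry magnitudes
uniform on $[0.5, 1.5]$, random signs — bounded away from zero so numeric
rank loss cannot masquerade as structural rank loss) and takes the maximum
SVD rank of the realized Kalman matrix over 8 trials, mirroring the
maximisation in the definition of generic rank. The test suite sweeps *all*
loop-free digraphs on 4 nodes (each also self-loop augmented), every driven
subset and every $T \le 4$, plus hundreds of random 5–6-node digraphs, and
requires exact agreement between the two routes.

## The self-loop reduction and its empirical bridge

Because the memory contributes a free diagonal, the minimum driven-node
count of a fractional network at any time-to-control coincides,
generically, with that of a *Markov* network on the same topology with
self-loops at all nodes. The package exposes this as a mode switch:
`mode = "long_memory"` dispatches every structural computation onto
`selfloop_augment(pattern)`; `mode = "markov"` uses the pattern unchanged.
Two consequences are checked as invariants: patterns that already carry all
self-loops give identical counts in both modes, and the long-memory count
never exceeds the Markov count.

The reduction itself (whose formal proof lives outside this package) is
verified *behaviorally*: for random fractional networks with heterogeneous
exponents $\alpha_i \sim U(0.2, 0.8)$, the structural verdict on the
augmented pattern agrees with the numeric rank of the fractional
$T$-step reachability map $x[T] = \sum_k G_{T-1-k} B u[k]$,
$G_m = \sum_{j<m} A_j G_{m-1-j}$, across every tested case. Heterogeneity
of the exponents matters: with identical $\alpha_i$ the diagonal
realizations are no longer generic (a star driven at the hub then loses a
rank — the Vandermonde-type gain needs distinct memory weights), which is
why the sampler draws $\alpha$ per node.

## Driven-node selection

Three certified selectors, all tie-breaking by smallest node index for
reproducibility:

* **exact** — subsets in increasing cardinality (lexicographic within a
  size), pruned by two necessary conditions: at least $\lceil N/T \rceil$
  nodes (each input contributes at most $T$ columns) and at least one node
  per **source SCC** (a strongly connected component with no incoming arcs
  is reachable only from within). Capped at $N \le 14$ ($2^{14}$ subsets
  of flow calls stay in seconds).
* **greedy** — adds the node with the largest generic-rank gain until rank
  $N$. The map from driven sets to generic rank is a matroid rank
  function, hence monotone submodular, which justifies an accelerated
  ("lazy") implementation: cached gains are upper bounds, and a candidate
  that cannot strictly beat the incumbent is skipped. Scanning candidates
  in index order makes the lazy variant *output-identical* to plain
  greedy, including the tie-break. Flow state is maintained incrementally
  across additions.
* **heuristic** — reconstruction of a scalable partition-based selection
  procedure that is described in the literature only in prose (its
  reference implementation and $O(n^2 \log n)$ complexity proof are not
  publicly available): seed one
  representative per source SCC; while rank is deficient, split the nodes
  (condensation topological order) into $\lceil N/T \rceil$ balanced
  blocks and add each block's induced source-SCC representatives; finish
  with greedy repair, prune removable nodes in reverse index order, and
  fall back to the plain greedy set if that is smaller. Because every
  result is certificate-checked, correctness never depends on matching
  that procedure — only minimality at scale may differ, and the
  `method` field records which selector produced a set.

`method = "auto"` (the default in sweeps) uses exact up to 14 nodes and the
heuristic beyond. Certificate soundness is tested both structurally (flow)
and numerically (random realizations) on every selector.

## Experiments and metrics

`control_profile()` sweeps a horizon grid (default: ~20 evenly spaced
values including 1 and $N$; a full sweep is $O(N)$ selections) and tabulates
$n_{\text{Markov}}$, $n_{\text{long-memory}}$, their difference $n_T$, and
the percentage metrics %D, % savings and % time-to-control. The metric
identities are asserted on every emitted profile rather than assumed, and
`% savings` is defined as 0 when $n_{\text{Markov}} = 0$ (unreachable for
$N \ge 1$, but guarded).

`ensemble_experiment()` averages profiles over seeded replicate networks at
matched % time-to-control. Scaled-down defaults — 20 replicates and sizes
in the tens — keep the suite at desk scale; the reference experimental
design (100 replicates, sizes 250/500/1000, ER edge surpluses 20/50/100%,
BA $k \in \{2,5,10\}$, WS $p \in \{0.2,0.5,0.8\}$) is one config away, and
per-replicate seeds are recorded for exact replay.

### Synthetic network generators

The three families mirror the experimental design's definitions:

* **Erdős–Rényi** `G(n, m)`: uniform over all *directed* graphs with
  exactly `m` arcs, no self-loops — the natural reading of "fixed nodes
  and edges" for an asymmetric state matrix.
* **Barabási–Albert**: classical preferential attachment (seed clique of
  $k$ nodes, $k$ degree-proportional attachments per new vertex),
  generated undirected and symmetrised into opposing arc pairs.
* **Watts–Strogatz**: ring lattice with `neighbors` nearest neighbours
  (default 4 — common reference settings list only $(n, p)$, and 4 is the
  smallest lattice degree that leaves small-world rewiring non-trivial),
  each edge rewired with probability $p$ avoiding duplicates and loops;
  also symmetrised.

BA/WS symmetrisation reflects their classical undirected definitions; it
has a visible consequence — symmetrised topologies are "easier" for Markov
dynamics (reciprocal arcs provide return walks), so their $n_T$ savings are
smaller than on directed ER graphs of similar density, and dense BA
($k = 10$) collapses to $n_T \approx 0$ while $k = 2$ retains a large gap
at high % time-to-control. A green ensemble test therefore establishes the
*direction* of these trends at desk scale, not reported magnitudes on
250–1000-node ensembles or on real connectomes (which also depend on the
unavailable reference selection algorithm).

What the generators do not emulate: degree correlations, clustering
profiles, or community structure of real connectomes; weighted coupling;
any temporal variation of topology.

## Multifractal spectrum

`sandbox_spectrum()` implements the sandbox method (chosen over
box-covering, which requires an NP-hard cover minimisation): for sampled
centers $c$, the ball masses $M_c(r)$ give

$$\tau(q) = \text{slope of } \ln \langle (M_c(r)/N)^{q-1} \rangle_c
\text{ vs } \ln (r/d),$$

fitted by least squares over radii where the mean relative mass has not
saturated (threshold 0.95; at least 3 usable radii are required, else the
computation refuses — small-diameter graphs cannot support a spectrum
estimate). $\alpha(q) = d\tau/dq$ by central differences on the
(non-uniform) $q$ grid, $f(\alpha) = q\alpha - \tau$. Defaults: 50
centers, radii $1..\lceil d/2 \rceil$, $q \in [-5, 5]$ in steps of 0.5
with the interval $(0.9, 1.1)$ excluded (the $q = 1$ moment needs a limit
form we deliberately avoid). Distances are computed on the symmetrised
graph; disconnected inputs are restricted to the giant component with a
warning.

"Height" has no single agreed definition; we use
$\max_q f(\alpha(q))$, which for a concave spectrum sits at $q = 0$ where
$f = -\tau(0)$ estimates the fractal dimension. On heterogeneous toys the
negative-$q$ wing is noisy (small-mass sandboxes dominate
$(M/N)^{q-1}$), so estimated spectra need not be concave; tests assert
exact monotonicity of $\alpha(q)$ only for the homogeneous ring and a loose
tolerance (0.1) for the hierarchical tree. The association tested is
directional: a ring lattice is near-monofractal (width < 0.2) while a
hierarchical tree of matched size is wider — mirroring the observation
that wider/taller spectra (more heterogeneous structure) accompany larger
driven-node savings.

## Numerical choices

* **Kernel**: $\Psi$ is computed by the multiplicative recurrence
  $\Psi(\alpha, j) = \Psi(\alpha, j-1)\,(j-1-\alpha)/j$, never by Gamma
  ratios at runtime ($\Gamma(-\alpha)$ poles at integer $\alpha$; overflow
  for large $j$); integer orders are handled exactly by the recurrence's
  zero factor. Validated against direct Gamma evaluation to $10^{-10}$
  relative error for $j \le 50$ and against the asymptotic log–log slope
  $-(1+\alpha)$ over $j \in [10^2, 10^4]$.
* **Simulation** is full-history (the model is infinite-memory up to $k$);
  horizons here are short enough that no truncation window is needed — a
  truncated variant would incur an $O(L^{-\alpha})$ tail error for window
  $L$.
* **Numeric rank**: singular values below
  $\max(\text{dim}) \cdot \varepsilon \cdot \sigma_{\max}$ count as zero
  (the standard rule; Armadillo's default coincides).
* **Randomness**: every stochastic operation takes an explicit integer
  seed, routed through an internal RNG-state-preserving helper; derived
  seeds stay below $2^{31}$. Ensemble replicates record their seeds.
* **Tie-breaks**: smallest node index, everywhere.

## Known limitations

* The minimum counts at scale are heuristic upper bounds (certified
  feasible, not certified minimal) beyond the 14-node exact cap.
* The sandbox spectrum depends on fit-range and center-count choices; its
  absolute width/height values are method-dependent and only comparisons
  under matched settings are meaningful.
* Real connectome/power-grid profiles require the user to supply those
  networks (edge list or Matrix Market); none ship with the package, and
  whether to symmetrise them is exposed as a flag rather than decided
  here.
* Energy/Gramian questions, exponent estimation from data, and input
  waveform design are out of scope.
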