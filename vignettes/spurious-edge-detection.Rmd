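---
title: "Detecting potentially spurious edges in delay-weighted interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting potentially spurious edges in delay-weighted interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spurnet)
```

## The problem

Bivariate (pairwise) reconstruction of directed interactions — for
example transfer entropy with interaction-delay reconstruction between
source time courses — produces networks in which some edges do not
correspond to a physical interaction. Two motifs dominate:

* **Cascade effect (CE).** Information flowing $v_s \to v_1 \to v_t$
  also produces an apparent direct interaction $v_s \to v_t$. The
  giveaway is timing: the apparent direct delay equals the summed delay
  along the indirect route.
* **Simple common drive (CD).** A node $v_s$ drives both $v_1$ and
  $v_t$ with different delays; the differential delay shows up as an
  apparent interaction $v_1 \to v_t$. In a triangle motif this has the
  same timing signature viewed from the other side, so CE and CD
  candidates come in pairs and at most one of the two can actually be
  spurious.

`spurnet` post-processes a directed graph $G = \{V, E\}$ whose edge
weights $w_{(v_i,v_j)} \ge 1$ are integer interaction delays. An edge
$(v_s, v_t)$ is tagged *potentially spurious* (CE) when at least one
**alternative path** exists: a simple path $v_s \rightsquigarrow v_t$
not using the edge itself whose summed delay lies within a user
threshold $\theta$ of the edge's own delay. Every alternative path of
graphical length 2 additionally identifies a triangle motif and yields
a CD tag on its second edge.

## The search algorithm

Deciding whether a weight-constrained path exists is handled by a
memoized dynamic program rather than path enumeration. For the examined
edge, the graph is reduced to $G'$ (edge removed), vertices are
relabeled so the start vertex has index 1 and the target index $|V|$,
and $G'$ is stored as an inverted adjacency list (per-vertex
predecessor lists). The table — the *solution array* — has one row per
path weight $0..w_{crit}$ with $w_{crit} = w_{(v_s,v_t)} + \theta$ and
one column per vertex. The cell at (row $w_i$, column $v_j$) collects
tuples $(w_{(v_p,v_j)}, v_p)$, one for each incoming edge of $v_j$
whose predecessor cell at row $w_i - w_{(v_p,v_j)}$ is non-empty; the
base cell at (0, $v_s$) holds the empty walk. Rows are filled in
increasing weight order (inner order: vertex index), so every
referenced subproblem is already solved. Treating one incoming edge is
one *algorithmic step*; the fill therefore costs exactly
$w_{crit}\cdot|E(G')|$ steps — linear in both the critical weight and
the edge count — and these counters are what the benchmark harness
records (wall-clock time is hardware-bound and is deliberately never
reported as a result).

Cells represent *walks* (vertex repeats allowed), which keeps the table
polynomial. Simple paths are recovered afterwards by depth-first
backtracking from every non-empty target-column cell whose row lies in
the closed *reconstruction interval*
$[w_{(v_s,v_t)} - \theta,\; w_{(v_s,v_t)} + \theta]$ (clamped below at
0): each tuple is expanded towards the start vertex, any expansion that
revisits a vertex on the partial path is discarded as a loop, and the
surviving vertex sequences are the alternative paths.

Two points in this formulation were genuinely open and are fixed as
follows:

* **Interval closure.** The reconstruction interval is *closed*;
  $\theta = 0$ means exact delay equality. This matches the cell range
  the backtracking stage reads (three rows $w-1, w, w+1$ at
  $\theta = 1$) and makes $\theta$ an inclusive tolerance.
* **Start-vertex column.** The start column holds only the base cell;
  for $w_i > 0$ it stays empty. A walk that re-enters the start vertex
  can only ever extend to a non-simple path, which backtracking would
  discard anyway, so leaving those cells empty prunes useless work
  without changing the output (this equivalence is exercised against a
  brute-force simple-path enumerator in the test suite). The
  brute-force walk oracle used to verify cell semantics is defined
  accordingly, over walks that visit the start only at the origin.

The number of valid reconstructed paths per edge is capped at a
**limit** (default 20000). Reaching the cap flags the edge
*intractable*: at least `limit` alternative paths exist, so the edge is
still CE-tagged, but enumeration is cut short. In dense random
topologies the number of candidate paths grows like the number of
compositions of the critical weight, $\sum_{j=1}^{i}\binom{i-1}{j-1} =
2^{\,i-1}$, i.e. exponentially in $w_{crit}$
(`expected_alt_path_count()` evaluates the corresponding analytic
estimate $\sum_{w'=1}^{w_{crit}}\sum_{j=1}^{w'}\binom{w'-1}{j-1}
(\rho/w_{max})^{j}$ verbatim; it is meaningful in the dense regime
$w_{crit} > |V|$ and ignores the weight cap, so outside that regime it
is only an order-of-magnitude guide).

## Tagging, triangles and pruning

`tag_cascade_effects()` runs the search for every edge *against the
full original graph minus only that edge*. Alternative paths found for
one edge are never invalidated by decisions about other edges, so no
sequential deletion takes place and the result is independent of edge
order (edges are nevertheless processed in deterministic lexicographic
order, and DFS expands predecessors in ascending vertex index, so
output ordering is reproducible).

`tag_common_drive()` scans each CE edge's length-2 alternative paths
$\langle v_s, v_1, v_t\rangle$ and adds one CD tag per distinct
triangle to the edge $(v_1, v_t)$. Both triangle edges are reported
even though at most one can truly be spurious: adjudicating between
them needs external (anatomical or modeling) evidence the graph does
not contain, so the decision is left to the prune policy.
General common drive over arbitrary-length cascades is out of scope by
design — it requires listing all paths of arbitrary length from every
node, a factorially expensive computation.

`prune_graph()` removes tagged edges under a policy (`all`, `ce-only`,
`cd-only`, `report-only`). Removing **all** tagged edges yields a
conservative sub-network guaranteed to contain non-spurious edges only,
at the cost of guaranteed false negatives inside triangle motifs; the
removal log flags those mutually exclusive pairs.

## Parameters

| parameter | meaning | default |
|---|---|---|
| $\theta$ | delay tolerance, in the same scaled integer units as the edge weights | none (user must choose) |
| `limit` | cap on reconstructed paths per edge | 20000 |
| `on_limit` | `mark` flags and continues; `abort` stops the run | `mark` |
| `scale` | linear factor applied to real-valued delays before rounding to integers | 1 |
| `w_max` | generator maximum edge weight | 17 |

$\theta$ should absorb the delay-reconstruction error — e.g. a
bootstrap standard error of the delay estimates, rounded up — and stay
below the smallest plausible interaction delay; too large a $\theta$
tags sound edges. Weights must be integers because the solution array
is indexed by weight; `quantize_weights()` is the sanctioned
conversion and warns when rounding at the chosen scale distorts any
delay by more than 10% (configurable). Delays reconstructed from MEG
source data typically span 5–17 ms at millisecond resolution, which
motivates both the default scale of 1 on millisecond integers and the
generator default `w_max = 17`.

## Synthetic networks

The generators produce the directed, delay-weighted test topologies
used throughout the tests, all with independent uniform integer weights
on $1..w_{max}$ drawn after the topology (in edge-lexicographic order,
so topology is comparable across `w_max` at a fixed seed):

* `gen_random(n, rho)` — each ordered pair included independently with
  probability $\rho = |E|/(|V|(|V|-1))$.
* `gen_small_world(n, neighbors, p_rewire)` — directed ring lattice
  (each node to its `neighbors` nearest ring neighbors, both sides)
  with independent rewiring; collisions are redrawn so the graph stays
  simple. Only the underlying undirected, unweighted lattice has
  textbook small-world properties.
* `gen_scale_free(n, m)` — preferential attachment under a documented
  fixed convention: complete-digraph seed on $m+1$ nodes, attachment
  probability proportional to total degree, direction new→old, giving
  exactly $m \cdot n$ edges. The power-law exponent is emergent and is
  neither estimated nor asserted.

What these graphs *do not* emulate: estimation noise (edges here are
exact, with no false positives/negatives from statistics upstream),
delay-estimation error (weights are exact integers; in real data
$\theta$ must absorb the error), and any anatomical structure. Passing
tests on these graphs therefore validate the graph algorithm, not the
upstream reconstruction pipeline.

## Problem sizes and the intractability contrast

The test suite verifies the search against an independent brute-force
simple-path enumerator on 200 random graphs ($|V| \le 8$,
$\rho \in \{0.3, 0.5\}$, weights $1..6$, $\theta \in \{0,1,2\}$),
checks $\theta$-monotonicity of the CE set and the self-extinguishing
property of full pruning on 50 graphs each, and confirms the step-count
law on every instance plus across $|V| \in \{10,\dots,50\}$ at fixed
density.

The qualitative tractability contrast between topologies is
demonstrated at a deliberately reduced scale chosen as follows:
$w_{max} = 5$ (rather than 17) moves the onset of path proliferation to
small critical weights, so the compositions-driven explosion is visible
at $w_{crit} = 14$ on 20-node graphs; the benchmark harness imposes a
grid $w_{crit}$ by giving each edge the tolerance
$\theta_e = \max(0, w_{crit} - w_e)$. Under this grid, dense random
networks ($\rho = 0.5$) contain edges that hit the 20000-path limit
while small-world networks ($\mathit{neighbors} = 6$,
$p_{rewire} = 0.1$) contain none, reproducing the ordering observed at
full scale. One caveat is documented deliberately: the small-world
condition uses the classic regime $\mathit{neighbors} \ll |V|$. At 20
nodes a lattice dense enough to match $\rho = 0.5$ has a neighborhood
window spanning half the ring; such a graph is not meaningfully
small-world — locally it behaves like the dense random case, path
proliferation included — so density matching and small-worldness cannot
be had simultaneously at this scale. The contrast shown is therefore a
topology-class contrast at matched size, not at matched density.

## Degenerate inputs and numerical choices

* Empty graphs, single-edge graphs and graphs whose reduced $G'$ has no
  edges are all legal; the search returns an empty result
  (`has_alternative = FALSE`).
* Weights $\ge 1$ bound walk length by $w_{crit}$, so termination is
  unconditional; there are no tolerances or floating-point comparisons
  anywhere in the search (all arithmetic is integer).
* A single-edge alternative is impossible by construction (the only
  $(v_s, v_t)$ edge was removed and parallel edges are forbidden), so
  every alternative path has graphical length $\ge 2$.
* An edge may carry both a CE tag and a CD tag (from a different
  triangle); tags are reported separately and never merged.
* The antiparallel partner $(v_t, v_s)$ of the examined edge, when
  present, participates in $G'$ like any other edge; simplicity
  checking during backtracking handles it with no special casing.
* `crossover_size(f)` computes the largest $|V|$ at which brute-force
  trivariate estimation is not yet more expensive than the two-stage
  approach from the closed form $(1-f)(|V|-2) \le 1$ and then verifies
  the boundary by direct cost comparison, avoiding floating-point
  edge effects near the threshold.

## Known limitations

* Only *simple* common drive (triangle motifs) is detected; general CD
  over longer cascades and synergistic multi-source effects are out of
  scope.
* Tags mark *potentially* spurious edges. The method is deliberately
  conservative: removing all tags trades false negatives for a
  guarantee of no false positives among the survivors.
* The expected-path-count formula is an upper-regime estimate, not a
  per-graph prediction.
* Intractable edges are CE-tagged on the strength of `limit` paths
  found, but their full path set is not enumerated.
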