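---
title: "Orbit-aware quad and triad censuses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orbit-aware quad and triad censuses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbcensus)
```

## What is being counted

A *quad* is any graph on four nodes, connected or not; there are eleven up
to isomorphism. A node of a quad has a *role* — its automorphism orbit —
and so does an edge: the claw distinguishes centre from leaf, the diamond
distinguishes its cycle edges from the diagonal. For a node $u$ of the
input graph and a quad orbit $o$, the *induced* count $ni_o(u)$ is the
number of 4-subsets containing $u$ whose induced subgraph places $u$ in
orbit $o$; the *non-induced* count $nn_o(u)$ counts pairs (4-subset, edge
subset) instead. Summing the induced node counts of a quad's orbits over
all nodes and dividing by four yields the graph-level census; the analogous
statements hold per edge and for directed triads (16 classes, 36 node
orbits).

Every 3- or 4-subset induces exactly one pattern, which gives the
conservation laws used throughout the tests: induced node counts sum to
$\binom{n-1}{3}$, edge counts to $\binom{n-2}{2}$, the graph census to
$\binom{n}{4}$, and triad counts to $\binom{n-1}{2}$ and $\binom{n}{3}$.

## The counting pipeline

**Ordering and orientation.** `smallest_last_order()` removes a
minimum-degree node repeatedly; directing each edge from its earlier to its
later endpoint (`orient_acyclic()`) yields an acyclic orientation whose
maximum outdegree equals the graph's degeneracy, itself below twice the
arboricity. Ties are broken by smallest internal index so the order — and
therefore all outputs — are deterministic. The ordering uses an ordered-set
priority structure: it pays a logarithmic factor over the classical bucket
queue but makes the pinned smallest-index tie-break exact; at the problem
sizes this package targets the difference is immaterial, and none of the
orientation's properties depend on it.

**The scan** (`quad_scan()`, compiled code) makes one pass over the
orientation:

* *Triangles*: for each node $u$, its out-neighbours are marked; an arc
  $v \to w$ between two marked nodes closes the triangle $\{u,v,w\}$,
  which is therefore listed exactly once, at its earliest node.
* *K4s*: a K4 appears as a triangle among the common out-neighbours of its
  two earliest nodes; a second marking layer finds those triangles, again
  listing each K4 once.
* *Non-induced C4s*: a four-cycle is two wedges with the same endpoints.
  Anchoring at the cycle node $z$ that is *latest* in the order, every
  wedge $z - v - w$ with $v, w$ earlier than $z$ is tallied by its far
  endpoint $w$; $c$ wedges to the same $w$ contribute $\binom{c}{2}$
  cycles, and a second pass distributes the counts to the four cycle nodes
  and edges. Anchoring at the latest node keeps the inner loops bounded by
  out-degrees times degrees, i.e. $O(a(G) \cdot m)$ overall, and counts
  each cycle exactly once.

The scan also accumulates the triangle-based aggregates the closed forms
need (sums over triangles at a node of the other two degrees and of the
opposite edge's triangle count, and their per-edge analogues), plus
inner-loop operation counters that the tests use to verify the scan scales
near-linearly in $m$ at fixed density rather than quadratically.

**Closed forms.** Each of the 20 + 14 non-induced orbit counts is a
closed-form combination of $n$, $m$, degrees, neighbour aggregates
($S(u) = \sum_{v \in N(u)} d(v)$, the analogous sums of $d^2$, of $S$
itself, and of triangle counts) and the scan statistics. Two anchors are
classical: $nn_{14}(u) = \sum_{\{v,w\} \in T(u)}(d(v)+d(w)-4)$ for the paw
with $u$ in the degree-2 triangle role, and
$en_4(u,v) = S(u)+S(v)-2(d(u)+d(v))+2-2t(u,v)$ for the P4 end edge. The
remaining formulas were derived by the same inclusion–exclusion reasoning;
each one is accepted only because it matches exhaustive enumeration on the
randomised suite (they are re-verified on every test run). Two second-order
neighbour aggregates (the neighbour sums of $S$ and of triangle counts)
are required beyond first-order degree sums; both are plain $O(m)$ passes.

**Induced counts.** Non-induced and induced counts are linked by
$nn = C \cdot ni$ where $C_{o,o'}$ counts the edge subsets of the denser
quad that form the sparser quad with the anchor's orbit mapped $o' \to o$.
`derive_quad_coefficients()` computes $C$ by exhaustive enumeration over
the $2^6$ labelled 4-node graphs rather than by transcription, because a
transcription error in a 20×20 integer table is nearly undetectable by
eye; the derived matrices are frozen as source constants and the test
suite asserts the regeneration matches, along with the hand-checkable
anchor row $ei_{10} = en_{10} - ei_{11} - 2\,ei_{13}$. $C$ is unitriangular
when orbits are sorted by the quad's edge count (a quad spans only
at-least-as-dense quads), so `induced_from_noninduced()` back-substitutes
in density order. All arithmetic is integer-exact: counts are kept in
doubles, which represent integers exactly below $2^{53}$ — far above
anything reachable at the sizes this package addresses ($\binom{n-1}{3}$
reaches $2^{53}$ only near $n \approx 4\cdot10^5$ on complete graphs). The
conversion validates non-negativity and integrality of every solution
component and aborts otherwise, since any violation proves an upstream
inconsistency.

## Directed triads

The triad census reuses the template. The underlying undirected graph
carries two boolean flags per edge recording the original arc directions,
so the dyad indicator $l(i,j)$ is O(1). Triads whose underlying graph is a
triangle (orbits 21–35) are counted by listing underlying triangles with
the same oriented scan and decoding each triple's 6-bit dyad code through
a 64-entry lookup table. The table is *generated*: all 64 labelled 3-node
digraphs are canonicalised over the 6 permutations, matched to the 16
standard M-A-N representatives, and node orbits are computed from each
class's automorphism group. Generation is guarded by structural checks
(16 distinct classes, code 0 ↦ 003 with orbits (0,0,0), code 63 ↦ 300 with
orbits (35,35,35), triangle classes occupying exactly orbits 21–35).

Orbits 0–20 never require triple enumeration. With per-node tallies of
mutual, out-only and in-only partners, every wedge-shaped pattern count is
a product or pairwise sum of neighbour tallies; these count *non-induced*
configurations, and subtracting one for each listed triangle (whose dyad
types are known) converts them exactly to induced counts. The single-edge
patterns use inclusion–exclusion over the union of the endpoints'
neighbourhoods, and the empty triad follows by complementation from
$\binom{n-1}{2}$. The whole step is $O(n + m)$ beyond triangle listing.

**Orbit numbering.** Class blocks are fixed (003 {0} … 300 {35}); within a
block, roles are sorted by the ascending lexicographic key (mutual degree,
out-degree, in-degree) of the role in the class representative. Any
injective, documented key would do — the census is invariant, only the
column labels move — but the key must be frozen, and this one is computable
from the representative alone. The same principle fixes the quad orbit
numbering: quads in density order, roles within a quad identified by
degree, which is unambiguous for every 4-node pattern.

## Generators and what the tests show

The test bed is fully synthetic and seeded. `gen_small_world()` produces a
ring lattice (each node tied to its $r$ nearest neighbours per side) with
each lattice edge independently rewired with probability $p$ to a uniform
vacant dyad — the edge count is preserved, clustering decays with $p$.
`gen_pref_attach()` grows a network where each arriving node attaches to
$r$ targets, degree-proportionally or, with probability $p$, uniformly
from its current neighbours-of-neighbours, biasing towards local closure;
the first $r+1$ nodes attach to all predecessors, giving exactly
$m = rn - \binom{r+1}{2}$ edges. `gen_gnp()` adds the independent-edge
model, for digraphs with an optional reciprocation probability, since
dyad-independent models alone underrepresent the mutual dyads that
distinguish many triad classes.

These generators probe the counting logic across densities, degeneracies
and reciprocity levels; they do not reproduce degree heavy tails, community
structure or degree–degree correlations of observed networks. That is the
right trade-off here because the algorithms are exact: a census that equals
brute-force enumeration on hundreds of random graphs of varied density is
correct on any graph, and the generators only need to exercise every code
path (isolated nodes, trees, cliques, dense and sparse regimes), not to be
statistically faithful. Claims the tests do *not* make: anything about
runtime constants on real-world degree distributions, and anything about
graphs large enough to overflow exact double arithmetic (see above).

Problem sizes were chosen to keep the whole suite fast while leaving no
code path unexercised: exhaustive quad enumeration runs on 200 random
graphs with $n \le 30$ (the oracle is $\Theta(\binom{n}{4} \cdot 2^6)$ per
graph), triad enumeration on 200 digraphs with $n \le 25$, and the
scalability check runs the full node-and-edge census on a 20,000-node,
100,000-edge small-world graph — a few seconds — comparing operation
counters against a half-size instance to exclude quadratic behaviour.

## Degenerate inputs and numerical choices

Graphs with fewer than four (three) nodes yield all-zero censuses, not
errors. Isolated nodes are legitimate and carry nonzero counts in the
disconnected orbits, which is why the edge-list reader accepts an explicit
node list. Duplicate edges and both orientations of an undirected edge are
deduplicated silently (the count is recorded on the graph object);
self-loops are rejected. Edges are keyed internally by the ordered pair
(min, max) of dense indices; external identifiers are arbitrary strings
and are never reordered. Ties in the removal order are broken by smallest
index; seeds control all generator randomness and the caller's RNG state
is always restored.

## Limitations

* Five-node censuses and the full directed quad census are out of scope;
  the package computes the class count of directed quads (218) by
  enumeration, which is the first ingredient such an extension would need,
  but the 218-class system itself is not implemented.
* The triad census is node-orbit-aware only; the edge-orbit-aware variant
  would follow the same triangle-listing route but is not implemented.
* Graphs are static and unweighted; there is no streaming input.
* K4 listing is $O(a(G)^2 m)$ — on graphs with both huge $m$ and large
  degeneracy this term dominates, and no approximate fallback is provided:
  all counts are exact by design.
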