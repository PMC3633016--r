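---
title: "Ordered backtracking for subgraph isomorphism: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordered backtracking for subgraph isomorphism: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rimatch)
```

## The problem and the model

Biological and chemical networks are queried by substructure: a motif in an
interaction network, a functional group in a compound, a contact pattern in a
protein map. Formally, a pattern graph $G = (V, E)$ and a target graph
$G' = (V', E')$ carry vertex labels $lab$ (and optionally edge labels
$\beta$), and a *match* is an injective map $M : V \to V'$ with
$lab(u) = lab(M(u))$ and $(u, v) \in E \Rightarrow (M(u), M(v)) \in E'$.
When target edges between mapped vertices are also required to have pattern
counterparts the match is an *induced* subgraph isomorphism; otherwise it is
a *monomorphism*. Both graphs are taken as directed; an undirected graph is
represented by its symmetric digraph (each edge stored in both orientations),
which lets one matcher serve both cases — the degree filter below then
automatically reduces to the single undirected inequality. Patterns must be
connected; self-loops and parallel edges are rejected at construction, since
the scoring sets below are defined over distinct vertices and the molecular
and interaction graphs this package is aimed at contain neither. "Unlabeled"
graphs are simply graphs whose vertices share one label, so the matcher has
no unlabeled special case.

All matches can be arranged in a *search-space tree*: each node is a
tentative (pattern vertex, target vertex) assignment, and root-to-leaf paths
of length $|V|$ that satisfy all constraints are matches. The craft is in
visiting as little of this tree as possible.

## The static search strategy

The matcher assigns pattern vertices in a fixed sequence $\mu$, computed
once from the pattern alone — never from the target, and identical on every
branch. The sequence is built greedily ("greatest constraint first"): the
first vertex is one with the maximum number of distinct neighbors, and each
subsequent step appends the unplaced vertex $u_m$ maximizing the
lexicographic triple

1. $|V_{m,vis}|$ — placed vertices adjacent to $u_m$: constraints that bind
   the moment $u_m$ is assigned;
2. $|V_{m,neig}|$ — placed vertices adjacent to some unplaced vertex that is
   itself adjacent to $u_m$: constraints one step ahead;
3. $|V_{m,unv}|$ — unplaced neighbors of $u_m$ with no neighbor among the
   placed: fresh territory, weighted least.

Adjacency here is direction-blind throughout. Alongside $\mu$, each vertex
records a *parent*: the earliest $\mu$-member adjacent to it. During search,
candidates for $\mu_i$ ($i \ge 1$) are exactly the target neighbors of the
parent's image; for a connected pattern every placed vertex after the first
has $|V_{vis}| \ge 1$, so every level below the root is edge-constrained.
Candidates are screened by four conditions, evaluated in order and each only
if the previous held: (1) neither endpoint of the tentative assignment is
already used; (2) vertex labels are equal; (3) the target vertex's in- and
out-degrees dominate the pattern vertex's (a pure filter); (4) every pattern
edge to an already-assigned vertex exists in the target (with edge-label
equality when enabled, and the reverse implication too in induced mode).
Nothing else: no propagation, no look-ahead, no domain updates mid-search.

Two choices the formulation leaves open are fixed as follows and are part of
this package's contract:

* **Tie-breaking.** Score ties (including the choice of the first vertex) are
  broken by lowest vertex id, everywhere. This makes the ordering a pure
  function of the pattern, hence testable and reproducible; no observable
  behavior depends on which tied vertex "would have been" chosen.
* **Reciprocal directed edges.** For directed patterns, a pair connected in
  both directions should count for more than a single arc. The magnitude is
  not canonical; here each scoring-set element contributes the number of
  directed edges (1 or 2) linking it — or, for the look-ahead set, its
  heaviest witness — to the candidate. Undirected patterns use plain set
  cardinalities, so the symmetric storage does not double scores.

## The matcher and its statistics

`enumerate_matches()` walks the tree depth-first, trying candidates in
ascending target id, so output order is deterministic. Level 0 has no
parent; its candidates are all target vertices (or the first vertex's
domain, below). `visited_nodes` counts every feasibility-checked
(pattern-vertex, target-vertex) pair. Counting granularity is not canonical
either — one could count expansions instead — so this definition is used
consistently and comparisons are only ever made between runs of this
package. The default `timeout` of 180 s mirrors common benchmarking
practice for this problem class; expiry returns the partial result flagged
`timed_out`, never an error. Edge-label checking is an independent toggle,
default off: most network queries ignore edge labels, and when present they
only add constraints.

## The initial-domain variant

`ri_domains()` precomputes, per pattern vertex $u$, the set
$D(u) = \{t : lab(t) = lab(u),\ \deg_{in}(t) \ge \deg_{in}(u),\
\deg_{out}(t) \ge \deg_{out}(u)\}$, then makes **exactly one** sweep over the
pattern edges: for $(u, v) \in E$, candidates of $u$ with no out-neighbor in
$D(v)$ are dropped, then candidates of $v$ with no in-neighbor in $D(u)$.
The sweep uses each just-updated domain as it proceeds, in edge input order.
Iterating to a fixpoint would re-create propagation-style inference — the
costly machinery this design deliberately avoids; one pass is cheap,
preserves every true match (a mapped vertex always has the mapped neighbor
required), and already collapses domains to singletons when target labels
are unique, which is why unique-label searches are the easy case: with
$|D| \le 1$ everywhere the search degenerates to verification, and visited
nodes grow far slower than quadratically in target size (the acceptance
script measures the log–log slope directly). During search, domains act only
as intersection filters on candidate sets; they are never updated. Because
every vertex a domain drops would have failed the same label/degree/edge
checks inside the search, the match set is provably unchanged and the
visited-node count can only shrink — both properties are asserted over
random instances in the test suite.

## Synthetic benchmark machinery

The generators reproduce the standard evaluation setting for this problem
family, at desk scale:

* `random_graph()` — uniform independent edge probability; the regime used
  for small correctness instances (targets of 4–8 vertices at
  $p \in \{0.2, 0.5, 0.8\}$, 1–4 labels).
* `mesh_graph()` — 2D/3D/4D lattices with exact closed-form edge counts.
* `bounded_valence_graph()` — connected random regular graphs (valence 3, 6,
  9 in the classical suite). Sampling delegates to igraph's k-regular
  generator with connectivity resampling; only the degree postcondition is
  contractual, not the sampling law.
* `assign_labels()` — uniform, discretized gaussian, or unique-per-vertex
  labels. The gaussian's width is not canonical; the default
  $\sigma = k/6$ puts the alphabet's ends at about three standard
  deviations, giving a pronounced but not degenerate center bias.
* `extract_pattern()` — connected subgraph growth by frontier edges:
  starting from a random edge, edges incident to the current vertex set are
  added until the budget is reached, so the result is connected and, by
  construction, a monomorphic subgraph under the returned correspondence.
  Density classes (dense / semidense / sparse) steer the vertex count toward
  25% / 50% / 90% of the edge count: the extractor prefers edges that bring
  in a new vertex while under the class's vertex budget $r \cdot
  |E_{pattern}|$ and edges closing onto existing vertices once at it, with a
  final-step rule closing one cycle if a sparse pattern would end as a tree.
  The steering mechanism is this package's own (only the target ratios are
  canonical); achieved mean ratios are measured by the acceptance script and
  land within a few percent of the targets on dense-enough targets, with a
  documented ±20% band. Ratios are computed on unordered adjacent pairs for
  undirected targets — a connected graph cannot have more vertices than
  undirected edges + 1, so the 90% class is only meaningful in those units.

All generators are pure functions of their seed.

What the synthetic data does *not* emulate: the degree heterogeneity,
clustering and label skew of real interaction networks and molecular graphs.
Passing the correctness properties on these instances demonstrates the
algorithms' exactness — every match found, none invented, domains sound —
on arbitrary small labeled digraphs, which is a property of the code, not of
any data distribution. It says nothing about wall-clock competitiveness on
genome-scale networks; this implementation is plain R, chosen for clarity
and auditability, and its constants are far from those of tuned C engines.

## Validation design

Correctness is anchored to `brute_force_matches()`, an independent
exhaustive enumerator that shares no search code with the matcher (it
enumerates all injective maps and checks complete assignments wholesale),
guarded to 8-vertex patterns and 10-vertex targets. The test suite compares
the matcher to it as *sets of mappings* — not counts — over hundreds of
seeded random instances in both modes and both variants, re-verifies every
reported mapping with a third, assignment-level checker, cross-checks one
unlabeled family against igraph's independent LAD matcher, and pins the
ordering to a naive per-step recomputation written directly from the set
definitions. Problem sizes (200 correctness instances; 500 ordering graphs
of up to 6 vertices; unique-label targets of 50–800 vertices; 100
extractions per density class at 64 edges) were chosen so the whole suite
runs in well under a minute of CPU; they are the package's validation
conditions, not tuning knobs.

## Known limitations

* No approximate or inexact matching; exact semantics only.
* The matcher is single-threaded, pure R; large dense unlabeled targets are
  out of its practical range.
* The one-pass domain filter is intentionally weaker than
  propagate-to-fixpoint filtering; on instances where inference pays, a
  LAD-style engine will visit fewer nodes (at higher per-node cost).
* Absolute visited-node counts are comparable only within this package,
  given the counting-granularity choice above.
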