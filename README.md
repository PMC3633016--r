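# rimatch

Exact subgraph matching in labeled graphs, for the kinds of questions that
come up across systems biology and chemistry: does this interaction motif
occur in a protein–protein interaction network, and where? How many times
does a functional substructure appear in each compound of a molecular
library? Both reduce to **subgraph isomorphism**: given a pattern graph
*G = (V, E)* and a target graph *G′ = (V′, E′)*, each with a vertex labeling
*lab* (and optionally an edge labeling *β*), find every injective map
*M : V → V′* such that *lab(u) = lab(M(u))* for all *u* and
*(u, v) ∈ E ⇒ (M(u), M(v)) ∈ E′*. Extra target edges between mapped vertices
are allowed for a *monomorphism* and forbidden for an *induced* subgraph
isomorphism; `rimatch` enumerates either.

The problem is NP-complete, so the engine's design is everything. `rimatch`
implements a backtracking matcher built around a **static, target-independent
variable ordering**: before any search, the pattern vertices are arranged in
a sequence μ by a greedy *greatest-constraint-first* rule — at each step the
unplaced vertex maximizing the lexicographic triple

> (placed neighbors, placed vertices reachable through one unplaced
> intermediate, fresh neighbors)

is appended, so edge constraints bind as early and as densely as possible on
every branch of the search tree. During search, candidates for each pattern
vertex come only from the target neighborhood of its *parent*'s image (the
earliest μ-member adjacent to it), and each candidate pair is screened by
four cheap conditions (injectivity, label equality, degree domination,
mapped-edge presence). No constraint propagation, no look-ahead inference:
the ordering carries the pruning. An optional **initial-domain variant**
additionally precomputes, once, the label/degree-compatible target
candidates of every pattern vertex plus a single edge-compatibility sweep —
it never changes the match set, only the work done, and pays off on large
dense targets.

The package also ships the benchmark machinery such matchers are evaluated
with: uniform random graphs, 2D/3D/4D mesh lattices, bounded-valence regular
graphs, label assignment (uniform, discretized gaussian, or unique per
vertex), connected pattern extraction with dense / semidense / sparse
density classes (vertex count ≈ 25% / 50% / 90% of the edge count), a
brute-force reference enumerator, and a suite driver with per-run search
statistics. Everything is seed-reproducible.

## Worked example

Build a small unlabeled random network, label it, pull out a connected
6-edge pattern, and search for it:

```r
library(rimatch)

target  <- assign_labels(random_graph(60, 0.15, seed = 42, name = "ppi_like"),
                         8, "uniform", seed = 43)
ext     <- extract_pattern(target, pattern_spec(6, "semidense", seed = 7))
pattern <- ext$pattern

tidy(greatest_constraint_first(pattern))
#> # A tibble: 7 x 6
#>    step vertex parent v_vis v_neig v_unv
#> 1     0      5     NA     0      0     3
#> 2     1      6      5     1      0     2
#> 3     2      1      5     1      0     1
#> 4     3      0      6     1      0     0
#> ...

enumerate_matches(pattern, target)
#> <ri_matches> 'ppi_like_pattern' in 'ppi_like' (monomorphism)
#>   82 matches, 1849 visited nodes, 0.021s
```

The ordering table reads: vertex 5 is placed first (3 neighbors, all fresh);
every later vertex already touches the partial ordering (`v_vis >= 1`), so
every search level below the root is edge-constrained. The matcher then
reports 82 monomorphic occurrences after expanding 1849 search-tree nodes.
The initial-domain variant finds the same 82 matches while visiting far
fewer nodes:

```r
dom <- ri_domains(pattern, target)
glance(enumerate_matches(pattern, target, domains = dom))
#> # A tibble: 1 x 6
#>   n_matches visited_nodes elapsed timed_out mode         used_domains
#> 1        82           220 0.009   FALSE     monomorphism TRUE
```

`tidy()` on a result gives one row per (match, pattern vertex, target
vertex); `ext$correspondence` — here `1 4 11 25 46 48 52` — is the
extraction's own embedding and is always among the matches.

A thin command-line front end wraps the same functions
(`inst/exec/ri`; subcommands `order`, `match`, `domains`, `gen`, `extract`,
`suite`, `oracle`), reading and writing a plain-text graph format documented
in `?read_graph`.

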