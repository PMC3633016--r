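Package: rimatch
Title: Subgraph Isomorphism Search with a Static Pattern-Vertex Ordering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact subgraph matching for labeled, directed or undirected graphs,
    as used for motif and substructure search in biological and chemical
    networks. Implements a static, target-independent pattern-vertex ordering
    (greatest-constraint-first) driving a lightweight backtracking matcher that
    enumerates monomorphisms or induced subgraph isomorphisms, an optional
    initial-domain filtering variant, synthetic benchmark generators (uniform
    random, mesh lattices, bounded-valence regular graphs, label assignment,
    connected pattern extraction by density class), a brute-force reference
    enumerator for validation, and a benchmark-suite driver with a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
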