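#' Uniform random graph
#'
#' Erdős–Rényi-style generator: every ordered vertex pair (directed) or
#' unordered pair (undirected) carries an edge independently with probability
#' `p`. All vertices receive the shared dummy label `"A"`; relabel with
#' [assign_labels()]. Bitwise-reproducible given `seed`.
#'
#' @param n Vertex count.
#' @param p Edge probability in `[0, 1]`.
#' @param directed Logical.
#' @param seed Integer seed.
#' @param name Graph name.
#' @return A [labeled_graph()].
#' @export
random_graph <- function(n, p, directed = FALSE, seed = 1L, name = "random") {
  n <- as.integer(n)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single probability in [0, 1]")
  withr::with_seed(seed, {
    if (n < 2L || p == 0) {
      em <- NULL
    } else if (directed) {
      pairs <- expand.grid(from = 0:(n - 1L), to = 0:(n - 1L))
      pairs <- pairs[pairs$from != pairs$to, ]
      keep <- stats::runif(nrow(pairs)) < p
      em <- as.matrix(pairs[keep, , drop = FALSE])
    } else {
      pairs <- t(utils::combn(0:(n - 1L), 2L))
      keep <- stats::runif(nrow(pairs)) < p
      em <- pairs[keep, , drop = FALSE]
    }
    labeled_graph(n, rep("A", n), em, directed = directed, name = name)
  })
}

#' Mesh (lattice) graph
#'
#' Regular grid in 2, 3 or 4 dimensions: vertices are coordinate tuples
#' (row-major ids, first coordinate varying fastest) and undirected edges join
#' tuples differing by 1 in exactly one coordinate.
#'
#' @param side_lengths Integer vector of 2--4 extents, each at least 2.
#' @param name Graph name.
#' @return An undirected [labeled_graph()] with `prod(side_lengths)` vertices
#'   and `sum over dimensions d of (extent_d - 1) * prod(other extents)`
#'   undirected edges.
#' @examples
#' mesh_graph(c(2, 2, 2))   # the cube: 8 vertices, 12 edges
#' @export
mesh_graph <- function(side_lengths, name = "mesh") {
  side_lengths <- as.integer(side_lengths)
  if (length(side_lengths) < 2L || length(side_lengths) > 4L)
    stop("mesh dimensionality must be 2, 3 or 4")
  if (any(is.na(side_lengths)) || any(side_lengths < 2L))
    stop("every mesh extent must be at least 2")
  ndim <- length(side_lengths)
  n <- prod(side_lengths)
  coords <- as.matrix(do.call(expand.grid, lapply(side_lengths, function(k) 0:(k - 1L))))
  strides <- cumprod(c(1L, side_lengths[-ndim]))
  from <- integer(0); to <- integer(0)
  for (d in seq_len(ndim)) {
    at <- which(coords[, d] < side_lengths[d] - 1L)
    from <- c(from, at - 1L)
    to <- c(to, at - 1L + strides[d])
  }
  labeled_graph(n, rep("A", n), cbind(from, to), directed = FALSE, name = name)
}

#' Bounded-valence (regular) random graph
#'
#' Connected random graph in which every vertex has exactly `valence`
#' undirected neighbors (the benchmark family uses 3, 6 and 9). Sampling uses
#' igraph's k-regular generator with resampling until a connected simple graph
#' is obtained; only the degree postcondition is contractual.
#'
#' @param n Vertex count; `n * valence` must be even and `n > valence`.
#' @param valence Required degree.
#' @param seed Integer seed.
#' @param name Graph name.
#' @return An undirected [labeled_graph()], all degrees equal to `valence`.
#' @export
bounded_valence_graph <- function(n, valence, seed = 1L, name = "valence") {
  n <- as.integer(n); valence <- as.integer(valence)
  if ((n * valence) %% 2L != 0L) stop("n * valence must be even")
  if (n <= valence) stop("need n > valence for a simple regular graph")
  withr::with_seed(seed, {
    for (try in 1:100) {
      ig <- igraph::sample_k_regular(n, valence, directed = FALSE, multiple = FALSE)
      if (igraph::is_connected(ig)) {
        em <- igraph::as_edgelist(ig, names = FALSE) - 1L
        return(labeled_graph(n, rep("A", n), em, directed = FALSE, name = name))
      }
    }
  })
  stop("failed to sample a connected regular graph after 100 attempts")
}

#' Assign vertex labels from a distribution over a label alphabet
#'
#' Vertices draw independently from `n_labels` symbols: equiprobably
#' (`"uniform"`), with probabilities proportional to a discretized gaussian
#' over the label indices (`"normal"`, mean at the center index), or --
#' modelling curated interaction networks where every protein is distinct --
#' `"unique"`, giving each vertex its own label.
#'
#' @param g A [labeled_graph()].
#' @param n_labels Alphabet size (ignored for `"unique"`). `n_labels = 1`
#'   reproduces the unlabeled regime.
#' @param distribution `"uniform"`, `"normal"` or `"unique"`.
#' @param seed Integer seed.
#' @param sigma Gaussian width in label-index units for `"normal"`; the
#'   default `n_labels / 6` spans the alphabet at about three standard
#'   deviations each side.
#' @return The graph with new `vertex_labels`.
#' @export
assign_labels <- function(g, n_labels, distribution = c("uniform", "normal", "unique"),
                          seed = 1L, sigma = NULL) {
  distribution <- match.arg(distribution)
  if (distribution == "unique") {
    labs <- sprintf("U%0*d", nchar(g$n_vertices), seq_len(g$n_vertices))
  } else {
    n_labels <- as.integer(n_labels)
    if (is.na(n_labels) || n_labels < 1L) stop("n_labels must be at least 1")
    alphabet <- sprintf("L%0*d", nchar(n_labels), seq_len(n_labels))
    prob <- if (distribution == "uniform") rep(1, n_labels) else {
      if (is.null(sigma)) sigma <- n_labels / 6
      stats::dnorm(seq_len(n_labels), mean = (n_labels + 1) / 2, sd = max(sigma, 1e-9))
    }
    labs <- withr::with_seed(seed,
      sample(alphabet, g$n_vertices, replace = TRUE, prob = prob))
  }
  labeled_graph(g$n_vertices, labs,
                if (g$directed) g$edges else g$edges[g$edges[, 1] < g$edges[, 2], , drop = FALSE],
                directed = g$directed, name = g$name, edge_labels = {
                  if (is.null(g$edge_labels)) NULL
                  else if (g$directed) g$edge_labels
                  else g$edge_labels[g$edges[, 1] < g$edges[, 2]]
                })
}

#' Pattern extraction request
#'
#' @param n_edges Edge budget for the extracted pattern (unordered adjacent
#'   pairs for undirected targets, directed edges otherwise).
#' @param density `"dense"`, `"semidense"` or `"sparse"`: the extractor steers
#'   the pattern's vertex count toward 25%, 50% or 90% of its edge count.
#' @param seed Integer seed.
#' @return A `pattern_spec` list.
#' @export
pattern_spec <- function(n_edges, density = c("dense", "semidense", "sparse"),
                         seed = 1L) {
  density <- match.arg(density)
  n_edges <- as.integer(n_edges)
  if (is.na(n_edges) || n_edges < 1L) stop("n_edges must be at least 1")
  structure(list(n_edges = n_edges, density = density, seed = as.integer(seed),
                 ratio = c(dense = 0.25, semidense = 0.5, sparse = 0.9)[[density]]),
            class = "pattern_spec")
}

#' Extract a connected pattern from a target graph
#'
#' Grows a connected subgraph by edges: starting from a random edge, edges
#' incident to the current pattern vertex set (the frontier) are added one at
#' a time until the budget is reached, so the result is always connected and,
#' by construction, a monomorphic subgraph of the target under the returned
#' correspondence (vertex and edge labels are copied). The density class
#' steers the choice between frontier edges that close onto existing pattern
#' vertices (keeping the vertex count down) and edges that bring in a new
#' vertex, tracking the class's vertex-to-edge ratio; for sparse patterns one
#' cycle is closed at the end if the pattern would otherwise be a tree.
#'
#' @param target A [labeled_graph()] with at least `spec$n_edges` edges (in
#'   the unit matching the target's directedness).
#' @param spec A [pattern_spec()].
#' @return List with `pattern` (a [labeled_graph()], vertices relabeled
#'   `0..k-1`) and `correspondence` (integer vector: element `u + 1` is the
#'   target id of pattern vertex `u`).
#' @export
extract_pattern <- function(target, spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  em <- target$edges
  if (!target$directed) em <- em[em[, 1L] < em[, 2L], , drop = FALSE]
  if (nrow(em) < spec$n_edges)
    stop("target has only ", nrow(em), " edges; ", spec$n_edges, " requested")
  r <- spec$ratio

  withr::with_seed(spec$seed, {
    # incidence of edge units on vertices (0-based target ids)
    start <- sample.int(nrow(em), 1L)
    in_pat_v <- logical(target$n_vertices)
    in_pat_e <- logical(nrow(em))
    vset <- unique(as.integer(em[start, ]))
    in_pat_v[vset + 1L] <- TRUE
    in_pat_e[start] <- TRUE
    chosen <- start
    # edges incident to each vertex, by unit row
    incid <- split(rep(seq_len(nrow(em)), 2L), c(em[, 1L], em[, 2L]))
    incid_of <- function(v) incid[[as.character(v)]]

    frontier <- setdiff(unique(unlist(lapply(vset, incid_of))), chosen)
    while (length(chosen) < spec$n_edges && length(frontier) > 0L) {
      both_in <- in_pat_v[em[frontier, 1L] + 1L] & in_pat_v[em[frontier, 2L] + 1L]
      v_now <- sum(in_pat_v)
      last_step <- length(chosen) + 1L == spec$n_edges
      # expanding past the class's vertex budget r * n_edges is avoided; a
      # sparse pattern that is still a tree closes one cycle on its last edge
      prefer_internal <- (v_now + 1L) > r * spec$n_edges ||
        (last_step && spec$density == "sparse" && v_now == length(chosen) + 1L)
      pool <- if (prefer_internal && any(both_in)) frontier[both_in]
              else if (!prefer_internal && any(!both_in)) frontier[!both_in]
              else frontier
      pick <- pool[sample.int(length(pool), 1L)]
      chosen <- c(chosen, pick)
      in_pat_e[pick] <- TRUE
      for (v in em[pick, ]) if (!in_pat_v[v + 1L]) {
        in_pat_v[v + 1L] <- TRUE
        frontier <- union(frontier, incid_of(v))
      }
      frontier <- frontier[!in_pat_e[frontier]]
    }

    tids <- sort(which(in_pat_v) - 1L)              # target ids in the pattern
    remap <- rep(NA_integer_, target$n_vertices)
    remap[tids + 1L] <- seq_along(tids) - 1L
    sub <- em[chosen, , drop = FALSE]
    sub_lab <- if (!is.null(target$edge_labels)) {
      key <- paste(em[chosen, 1L], em[chosen, 2L])
      unname(edge_label_map(target)[key])
    }
    pat <- labeled_graph(length(tids), target$vertex_labels[tids + 1L],
                         cbind(remap[sub[, 1L] + 1L], remap[sub[, 2L] + 1L]),
                         directed = target$directed,
                         name = paste0(target$name, "_pattern"),
                         edge_labels = sub_lab)
    list(pattern = pat, correspondence = tids)
  })
}
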