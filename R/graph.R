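#' Labeled graph container
#'
#' Constructs the graph object shared by patterns and targets: a simple
#' directed graph (no self-loops, no parallel edges) with one label per vertex
#' and optional edge labels. Undirected graphs are stored on their symmetric
#' digraph encoding -- each undirected edge becomes the two ordered pairs
#' `(u,v)` and `(v,u)` -- so the matcher never needs an undirected special
#' case. Vertex ids are dense 0-based integers, matching the on-disk format.
#'
#' @param n_vertices Number of vertices; vertex ids are `0:(n_vertices-1)`.
#' @param vertex_labels Character vector of length `n_vertices`. A graph with a
#'   single shared label plays the role of an unlabeled graph.
#' @param edges Two-column integer matrix or data frame of 0-based endpoint
#'   pairs. For `directed = FALSE` each undirected edge may be listed in either
#'   (or, redundantly, both) orientations; it is stored symmetrically.
#' @param directed Logical; interpretation of `edges`.
#' @param name Identifier string.
#' @param edge_labels Optional character vector, one label per row of `edges`.
#'   For undirected graphs the label is shared by both orientations.
#' @return An object of class `labeled_graph` with fields `name`, `directed`,
#'   `n_vertices`, `vertex_labels`, `edges` (ordered-pair matrix), and derived
#'   adjacency (`out_adj`, `in_adj`, 0-based neighbor vectors indexed by
#'   vertex id + 1).
#' @examples
#' tri <- labeled_graph(3, c("C", "C", "N"),
#'                      rbind(c(0, 1), c(1, 2), c(2, 0)), directed = FALSE)
#' graph_neighbors(tri, 0)
#' @export
labeled_graph <- function(n_vertices, vertex_labels, edges = NULL,
                          directed = TRUE, name = "g", edge_labels = NULL) {
  n_vertices <- as.integer(n_vertices)
  if (length(n_vertices) != 1L || is.na(n_vertices) || n_vertices < 0L)
    stop("n_vertices must be a single non-negative integer")
  vertex_labels <- as.character(vertex_labels)
  if (length(vertex_labels) != n_vertices)
    stop("need exactly one vertex label per vertex (got ", length(vertex_labels),
         " for ", n_vertices, " vertices)")
  if (anyNA(vertex_labels)) stop("vertex labels must not be NA")

  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(integer(0), ncol = 2L)
    edge_labels_in <- NULL
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "integer"
    edge_labels_in <- if (!is.null(edge_labels)) as.character(edge_labels)
    if (!is.null(edge_labels_in) && length(edge_labels_in) != nrow(em))
      stop("edge_labels must have one entry per edge")
  }
  if (nrow(em) > 0L) {
    if (anyNA(em)) stop("edge endpoints must not be NA")
    if (any(em < 0L) || any(em >= n_vertices))
      stop("edge endpoint out of range [0, ", n_vertices, ")")
    if (any(em[, 1L] == em[, 2L])) stop("self-loops are not allowed")
  }

  if (!directed && nrow(em) > 0L) {
    # canonicalize to unordered pairs, then expand symmetrically
    lo <- pmin(em[, 1L], em[, 2L]); hi <- pmax(em[, 1L], em[, 2L])
    key <- paste(lo, hi)
    keep <- !duplicated(key)
    if (!is.null(edge_labels_in)) {
      # a pair listed twice must agree on its label
      for (k in unique(key)) {
        labs <- unique(edge_labels_in[key == k])
        if (length(labs) > 1L)
          stop("conflicting edge labels for undirected pair ", k)
      }
      edge_labels_in <- edge_labels_in[keep]
      edge_labels_in <- rep(edge_labels_in, 2L)
    }
    lo <- lo[keep]; hi <- hi[keep]
    em <- cbind(c(lo, hi), c(hi, lo))
    storage.mode(em) <- "integer"
  } else if (nrow(em) > 0L) {
    if (anyDuplicated(paste(em[, 1L], em[, 2L])))
      stop("duplicate (parallel) edges are not allowed")
  }

  g <- structure(
    list(name = as.character(name), directed = isTRUE(directed),
         n_vertices = n_vertices, vertex_labels = vertex_labels,
         edges = em, edge_labels = edge_labels_in),
    class = "labeled_graph")
  g$out_adj <- adjacency_lists(n_vertices, em[, 1L], em[, 2L])
  g$in_adj  <- adjacency_lists(n_vertices, em[, 2L], em[, 1L])
  g
}

adjacency_lists <- function(n, from, to) {
  adj <- rep(list(integer(0)), n)
  if (length(from)) {
    sp <- split(to, factor(from, levels = 0:(n - 1L)))
    adj <- unname(lapply(sp, function(v) sort(as.integer(v))))
  }
  adj
}

#' @export
print.labeled_graph <- function(x, ...) {
  m <- nrow(x$edges)
  cat(sprintf("<labeled_graph '%s'> %s, %d vertices, %s\n",
              x$name, if (x$directed) "directed" else "undirected",
              x$n_vertices,
              if (x$directed) paste0(m, " edges")
              else paste0(m %/% 2L, " undirected edges (", m, " arcs)")))
  cat("labels:", paste(utils::head(unique(x$vertex_labels), 8L), collapse = " "),
      if (length(unique(x$vertex_labels)) > 8L) "..." else "", "\n")
  invisible(x)
}

check_vertex <- function(g, u) {
  u <- as.integer(u)
  if (length(u) != 1L || is.na(u) || u < 0L || u >= g$n_vertices)
    stop("invalid vertex id ", u, " for graph with ", g$n_vertices, " vertices")
  u
}

#' Neighbors of a vertex, ignoring edge direction
#'
#' The ordering and matching machinery treats the neighbors of `u` as every
#' vertex touching `u` by an edge in either direction.
#'
#' @param g A [labeled_graph()].
#' @param u 0-based vertex id.
#' @return Sorted integer vector of 0-based neighbor ids.
#' @export
graph_neighbors <- function(g, u) {
  u <- check_vertex(g, u)
  sort(unique(c(g$out_adj[[u + 1L]], g$in_adj[[u + 1L]])))
}

#' Vertex degrees
#'
#' @param g A [labeled_graph()].
#' @return Tibble with one row per vertex: `vertex`, `label`, `out_degree`,
#'   `in_degree`, `n_neighbors` (distinct adjacent vertices, direction-blind).
#' @export
graph_degrees <- function(g) {
  tibble::tibble(
    vertex = 0:(g$n_vertices - 1L),
    label = g$vertex_labels,
    out_degree = lengths(g$out_adj),
    in_degree = lengths(g$in_adj),
    n_neighbors = vapply(seq_len(g$n_vertices),
                         function(i) length(unique(c(g$out_adj[[i]], g$in_adj[[i]]))),
                         integer(1)))
}

#' Convert to / from igraph
#'
#' Interop with the igraph ecosystem. `as_igraph` keeps vertex labels in the
#' vertex attribute `label` and shifts ids to igraph's 1-based convention; an
#' undirected `labeled_graph` maps to an undirected igraph (one edge per
#' symmetric pair).
#'
#' @param g A [labeled_graph()].
#' @return An `igraph` object.
#' @export
as_igraph <- function(g) {
  em <- g$edges
  if (!g$directed && nrow(em)) em <- em[em[, 1L] < em[, 2L], , drop = FALSE]
  ig <- igraph::make_empty_graph(n = g$n_vertices, directed = g$directed)
  if (nrow(em)) ig <- igraph::add_edges(ig, as.integer(t(em)) + 1L)
  igraph::set_vertex_attr(ig, "label", value = g$vertex_labels)
}

#' Is the graph connected (direction-blind)?
#'
#' Connectivity of the underlying undirected skeleton; patterns must be
#' connected for the ordering and matcher to be defined.
#'
#' @param g A [labeled_graph()].
#' @return Logical scalar. The empty graph is not connected.
#' @export
graph_is_connected <- function(g) {
  if (g$n_vertices == 0L) return(FALSE)
  if (g$n_vertices == 1L) return(TRUE)
  igraph::is_connected(as_igraph(g), mode = "weak")
}

edge_label_map <- function(g) {
  if (is.null(g$edge_labels)) return(NULL)
  stats::setNames(g$edge_labels, paste(g$edges[, 1L], g$edges[, 2L]))
}

has_edge <- function(g, u, v) {
  v %in% g$out_adj[[u + 1L]]
}

#' Read a graph from its plain-text edge-list format
#'
#' Format, one graph per file: line 1 `#<name>`; line 2 the vertex count `n`;
#' then `n` label lines (the label of vertex `i` on the i-th); then the edge
#' count `m`; then `m` lines `<u> <v>` or `<u> <v> <edge-label>` with 0-based
#' endpoints. Directedness is declared by the caller, not stored in the file;
#' with `directed = FALSE` each listed edge is stored in both orientations.
#'
#' @param path File path.
#' @param directed Logical; how to interpret edge lines.
#' @return A [labeled_graph()].
#' @export
read_graph <- function(path, directed = TRUE) {
  lines <- readLines(path, warn = FALSE)
  bad <- function(i, msg) stop(sprintf("%s:%d: %s", path, i, msg), call. = FALSE)
  if (length(lines) < 2L) bad(1L, "file too short")
  if (!startsWith(lines[1L], "#")) bad(1L, "expected '#<name>' header")
  name <- sub("^#", "", lines[1L])
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n) || n < 0L) bad(2L, "invalid vertex count")
  if (length(lines) < 2L + n + 1L) bad(length(lines), "truncated vertex label block")
  labels <- trimws(lines[seq_len(n) + 2L])
  if (any(labels == "")) bad(which(labels == "")[1L] + 2L, "empty vertex label")
  mline <- 2L + n + 1L
  m <- suppressWarnings(as.integer(trimws(lines[mline])))
  if (is.na(m) || m < 0L) bad(mline, "invalid edge count")
  if (length(lines) < mline + m) bad(length(lines), "truncated edge block")
  em <- matrix(integer(0), ncol = 2L)
  elab <- character(0)
  any_elab <- FALSE
  if (m > 0L) {
    em <- matrix(NA_integer_, nrow = m, ncol = 2L)
    elab <- rep(NA_character_, m)
    for (k in seq_len(m)) {
      ln <- mline + k
      parts <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1L]]
      if (length(parts) < 2L || length(parts) > 3L) bad(ln, "expected '<u> <v> [label]'")
      uv <- suppressWarnings(as.integer(parts[1:2]))
      if (anyNA(uv)) bad(ln, "non-integer endpoint")
      if (any(uv < 0L) || any(uv >= n)) bad(ln, "vertex id out of range")
      if (uv[1L] == uv[2L]) bad(ln, "self-loop not allowed")
      em[k, ] <- uv
      if (length(parts) == 3L) { elab[k] <- parts[3L]; any_elab <- TRUE }
    }
    if (any_elab && anyNA(elab)) bad(mline + which(is.na(elab))[1L],
                                     "edge label missing (labels must be all-or-none)")
    key <- if (directed) paste(em[, 1L], em[, 2L])
           else paste(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L]))
    if (anyDuplicated(key)) bad(mline + which(duplicated(key))[1L], "duplicate edge")
  }
  labeled_graph(n, labels, em, directed = directed, name = name,
                edge_labels = if (any_elab) elab)
}

#' Write a graph in the plain-text edge-list format
#'
#' Inverse of [read_graph()]: `read_graph(write_graph(g, f), g$directed)`
#' reproduces `g` exactly. Undirected graphs emit each symmetric pair once
#' (low id first).
#'
#' @param g A [labeled_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path) {
  em <- g$edges
  elab <- g$edge_labels
  if (!g$directed && nrow(em)) {
    keep <- em[, 1L] < em[, 2L]
    if (!is.null(elab)) elab <- elab[keep]
    em <- em[keep, , drop = FALSE]
  }
  edge_lines <- if (nrow(em) == 0L) character(0)
    else if (is.null(elab)) paste(em[, 1L], em[, 2L])
    else paste(em[, 1L], em[, 2L], elab)
  writeLines(c(paste0("#", g$name), g$n_vertices, g$vertex_labels,
               nrow(em), edge_lines), path)
  invisible(path)
}
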