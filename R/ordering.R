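#' Score a candidate pattern vertex against a partial ordering
#'
#' The greedy ordering ranks each not-yet-placed vertex `u_m` by a
#' lexicographic triple of set sizes computed from the pattern alone:
#'
#' * `v_vis` -- placed vertices adjacent to the candidate (the constraint the
#'   candidate would add immediately);
#' * `v_neig` -- placed vertices adjacent to at least one unplaced vertex that
#'   is itself adjacent to the candidate (constraints one step ahead);
#' * `v_unv` -- unplaced neighbors of the candidate with no neighbor among the
#'   placed vertices (fresh exploration).
#'
#' Adjacency is direction-blind. For directed patterns a set element linked to
#' the candidate by both directed edges of a reciprocal pair weighs 2 instead
#' of 1 (for `v_neig`, the weight of the heaviest candidate--witness link);
#' undirected patterns use plain cardinalities.
#'
#' @param pattern A connected [labeled_graph()].
#' @param mu_prefix Integer vector of already-placed 0-based vertex ids (may be
#'   empty).
#' @param candidate 0-based vertex id, not in `mu_prefix`.
#' @return A `score_triple`: named integer vector `c(v_vis, v_neig, v_unv)`.
#' @export
score_candidate <- function(pattern, mu_prefix, candidate) {
  g <- pattern
  candidate <- check_vertex(g, candidate)
  mu_prefix <- as.integer(mu_prefix)
  if (candidate %in% mu_prefix)
    stop("candidate ", candidate, " is already in the ordering prefix")

  # weight of the link between candidate c and vertex x: number of directed
  # edges between them for directed patterns, else presence (0/1)
  wlink <- function(a, b) {
    w <- (b %in% g$out_adj[[a + 1L]]) + (b %in% g$in_adj[[a + 1L]])
    if (!g$directed) min(w, 1L) else w
  }
  in_mu <- logical(g$n_vertices)
  in_mu[mu_prefix + 1L] <- TRUE
  nb_c <- graph_neighbors(g, candidate)
  outside <- setdiff(setdiff(0:(g$n_vertices - 1L), mu_prefix), candidate)

  v_vis <- 0L
  for (x in nb_c[in_mu[nb_c + 1L]]) v_vis <- v_vis + wlink(candidate, x)

  # witnesses: unplaced (non-candidate) neighbors of the candidate
  witnesses <- intersect(nb_c, outside)
  v_neig <- 0L
  for (x in mu_prefix) {
    nb_x <- graph_neighbors(g, x)
    wts <- intersect(witnesses, nb_x)
    if (length(wts))
      v_neig <- v_neig + max(vapply(wts, function(j) wlink(candidate, j), integer(1)))
  }

  v_unv <- 0L
  for (j in witnesses) {
    nb_j <- graph_neighbors(g, j)
    if (!any(in_mu[nb_j + 1L])) v_unv <- v_unv + wlink(candidate, j)
  }

  structure(c(v_vis = as.integer(v_vis), v_neig = as.integer(v_neig),
              v_unv = as.integer(v_unv)),
            class = "score_triple")
}

#' @export
print.score_triple <- function(x, ...) {
  cat(sprintf("(v_vis=%d, v_neig=%d, v_unv=%d)\n", x[1L], x[2L], x[3L]))
  invisible(x)
}

#' Compare two score triples lexicographically
#'
#' @param a,b `score_triple`s.
#' @return -1, 0, or 1 as `a` is less than, equal to, or greater than `b`.
#' @export
compare_scores <- function(a, b) {
  for (k in 1:3) {
    if (a[[k]] > b[[k]]) return(1L)
    if (a[[k]] < b[[k]]) return(-1L)
  }
  0L
}

#' Static pattern-vertex ordering (greatest-constraint-first)
#'
#' Computes the search strategy used by the matcher: a sequence `mu` over the
#' pattern vertices, built greedily so that each appended vertex maximizes the
#' lexicographic [score_candidate()] triple among all unplaced vertices, plus a
#' parent pointer per vertex (the earliest `mu`-member adjacent to it, whose
#' matched image supplies the candidate targets during search). The ordering
#' depends only on the pattern -- never on any target.
#'
#' The first vertex is the one with the most distinct neighbors; all ties
#' (first vertex and every later step) break to the lowest vertex id, making
#' the result deterministic.
#'
#' @param pattern A connected [labeled_graph()] with at least one vertex.
#' @return An object of class `ri_ordering`: list with `mu` (0-based vertex
#'   sequence), `parent` (integer vector indexed by vertex id + 1, `NA` for the
#'   root), and `scores` (the winning triple at each step, as a matrix).
#' @examples
#' p <- labeled_graph(3, rep("A", 3), rbind(c(0, 1), c(1, 2)), directed = FALSE)
#' greatest_constraint_first(p)$mu   # 1 first: it has two neighbors
#' @export
greatest_constraint_first <- function(pattern) {
  g <- pattern
  if (g$n_vertices == 0L) stop("cannot order an empty pattern")
  if (!graph_is_connected(g)) stop("pattern must be connected")

  n <- g$n_vertices
  deg <- vapply(0:(n - 1L), function(u) length(graph_neighbors(g, u)), integer(1))
  mu <- integer(n)
  mu[1L] <- which.max(deg) - 1L          # which.max takes the first (lowest id) max
  placed <- logical(n)
  placed[mu[1L] + 1L] <- TRUE
  scores <- matrix(0L, nrow = n, ncol = 3L,
                   dimnames = list(NULL, c("v_vis", "v_neig", "v_unv")))
  scores[1L, ] <- c(0L, 0L, if (g$directed) {
    sum(vapply(graph_neighbors(g, mu[1L]), function(v)
      (v %in% g$out_adj[[mu[1L] + 1L]]) + (v %in% g$in_adj[[mu[1L] + 1L]]),
      integer(1)))
  } else deg[mu[1L] + 1L])

  if (n > 1L) {
    for (m in 2:n) {
      prefix <- mu[seq_len(m - 1L)]
      best <- -1L; best_score <- NULL
      for (cand in which(!placed) - 1L) {
        s <- score_candidate(g, prefix, cand)
        if (is.null(best_score) || compare_scores(s, best_score) > 0L) {
          best <- cand; best_score <- s
        }
      }
      mu[m] <- best
      placed[best + 1L] <- TRUE
      scores[m, ] <- unclass(best_score)
    }
  }

  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)[-1L]) {
    v <- mu[i]
    nb <- graph_neighbors(g, v)
    pos <- match(mu[seq_len(i - 1L)], nb)
    hit <- which(!is.na(pos))
    if (length(hit)) parent[v + 1L] <- mu[hit[1L]]
  }

  structure(list(mu = mu, parent = parent, scores = scores,
                 n_vertices = n, pattern_name = g$name),
            class = "ri_ordering")
}

#' @export
print.ri_ordering <- function(x, ...) {
  cat(sprintf("<ri_ordering> pattern '%s', %d vertices\n",
              x$pattern_name, x$n_vertices))
  p <- x$parent[x$mu + 1L]
  cat("mu:    ", paste(x$mu, collapse = " "), "\n")
  cat("parent:", paste(ifelse(is.na(p), "-", p), collapse = " "), "\n")
  invisible(x)
}

#' @rdname tidiers
#' @method tidy ri_ordering
#' @export
tidy.ri_ordering <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$mu) - 1L,
    vertex = x$mu,
    parent = x$parent[x$mu + 1L],
    v_vis = x$scores[, 1L], v_neig = x$scores[, 2L], v_unv = x$scores[, 3L])
}
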