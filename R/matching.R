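#' Match mode descriptor
#'
#' Two match semantics are supported. A *monomorphism* maps every pattern
#' vertex to a distinct target vertex preserving vertex labels and every
#' pattern edge; target edges between mapped vertices with no pattern
#' counterpart are allowed. An *induced* subgraph isomorphism additionally
#' forbids them. Edge-label checking is an independent toggle, off by default:
#' labels on edges add constraints but most network searches ignore them.
#'
#' @param mode `"monomorphism"` or `"induced"` (prefix-matched).
#' @param edge_labels Logical; require equality of edge labels along mapped
#'   pattern edges.
#' @return A `match_mode` list with fields `induced` and `edge_labels`.
#' @export
match_mode <- function(mode = c("monomorphism", "induced"), edge_labels = FALSE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, induced = identical(mode, "induced"),
                 edge_labels = isTRUE(edge_labels)),
            class = "match_mode")
}

as_match_mode <- function(mode, edge_labels = FALSE) {
  if (inherits(mode, "match_mode")) mode else match_mode(mode, edge_labels)
}

#' Candidate target vertices for the next search level
#'
#' At level 0 (the ordering's root has no parent) every target vertex is a
#' candidate; at deeper levels only the target neighbors (either direction) of
#' the parent's image are. When a precomputed domain table is supplied the set
#' is additionally intersected with the domain of the pattern vertex at this
#' level.
#'
#' @param target A [labeled_graph()].
#' @param ordering An `ri_ordering` for the pattern.
#' @param partial Integer mapping vector (index = pattern vertex id + 1, value
#'   = 0-based target id, `NA` when unassigned); levels `0..i-1` of the
#'   ordering must be assigned.
#' @param i 0-based level index.
#' @param domains Optional `domain_table` from [ri_domains()].
#' @return Sorted integer vector of candidate 0-based target ids (possibly
#'   empty, which simply triggers backtracking).
#' @export
candidate_targets <- function(target, ordering, partial, i, domains = NULL) {
  u <- ordering$mu[i + 1L]
  if (i == 0L || is.na(ordering$parent[u + 1L])) {
    cand <- 0:(target$n_vertices - 1L)
  } else {
    pimg <- partial[ordering$parent[u + 1L] + 1L]
    if (is.na(pimg)) stop("parent of level ", i, " is unassigned")
    cand <- graph_neighbors(target, pimg)
  }
  if (!is.null(domains)) cand <- intersect(cand, domains[[u + 1L]])
  as.integer(cand)
}

#' Feasibility of extending a partial mapping by one pair
#'
#' Applies the pruning conditions in their fixed order, each evaluated only if
#' the previous one holds: (1) neither the pattern vertex nor the target
#' vertex is already used; (2) equal vertex labels; (3) the target vertex has
#' at least the pattern vertex's degree (in- and out-degree separately for
#' directed graphs -- a cheap filter); (4) every pattern edge between `u` and
#' an assigned vertex has its counterpart in the target (with equal edge
#' labels when requested), and in induced mode every target edge between `t`
#' and an assigned image is mirrored by a pattern edge.
#'
#' @param pattern,target [labeled_graph()]s.
#' @param partial Mapping vector as in [candidate_targets()].
#' @param u Unassigned 0-based pattern vertex.
#' @param t Candidate 0-based target vertex.
#' @param mode A [match_mode()] (or mode string).
#' @return Logical scalar.
#' @export
is_feasible <- function(pattern, target, partial, u, t, mode = match_mode()) {
  mode <- as_match_mode(mode)
  u <- check_vertex(pattern, u); t <- check_vertex(target, t)
  if (!is.na(partial[u + 1L])) stop("pattern vertex ", u, " is already assigned")

  # condition 1: injectivity over the current path
  if (t %in% partial) return(FALSE)
  # condition 2: vertex label compatibility
  if (pattern$vertex_labels[u + 1L] != target$vertex_labels[t + 1L]) return(FALSE)
  # condition 3: degree filter
  if (length(target$out_adj[[t + 1L]]) < length(pattern$out_adj[[u + 1L]])) return(FALSE)
  if (length(target$in_adj[[t + 1L]]) < length(pattern$in_adj[[u + 1L]])) return(FALSE)
  # condition 4: edge constraints against already-assigned vertices
  assigned <- which(!is.na(partial)) - 1L
  pel <- if (mode$edge_labels) edge_label_map(pattern)
  tel <- if (mode$edge_labels) edge_label_map(target)
  for (v in assigned) {
    mv <- partial[v + 1L]
    if (has_edge(pattern, u, v)) {
      if (!has_edge(target, t, mv)) return(FALSE)
      if (mode$edge_labels &&
          !identical(pel[[paste(u, v)]], tel[[paste(t, mv)]])) return(FALSE)
    }
    if (has_edge(pattern, v, u)) {
      if (!has_edge(target, mv, t)) return(FALSE)
      if (mode$edge_labels &&
          !identical(pel[[paste(v, u)]], tel[[paste(mv, t)]])) return(FALSE)
    }
    if (mode$induced) {
      if (has_edge(target, t, mv) && !has_edge(pattern, u, v)) return(FALSE)
      if (has_edge(target, mv, t) && !has_edge(pattern, v, u)) return(FALSE)
    }
  }
  TRUE
}

#' Enumerate subgraph matches by ordered backtracking
#'
#' Depth-first traversal of the search-space tree: pattern vertices are
#' assigned in the static [greatest_constraint_first()] order, candidate
#' targets at each level are drawn from the neighbors of the parent's image
#' (all target vertices at the root, or the precomputed domain when the
#' initial-domain variant is active), and each candidate pair is screened by
#' [is_feasible()] before descending. Every complete assignment is reported
#' exactly once, in depth-first discovery order with candidates tried in
#' ascending target id, so runs are deterministic.
#'
#' `visited_nodes` counts every feasibility-checked (pattern-vertex, target
#' vertex) pair -- the search-space size, a hardware-independent measure of
#' effort.
#'
#' @param pattern Connected [labeled_graph()].
#' @param target [labeled_graph()]; a pattern larger than the target simply
#'   yields zero matches.
#' @param mode A [match_mode()] or mode string.
#' @param ordering Optional precomputed `ri_ordering` (any valid ordering gives
#'   the same match set; only the statistics may differ).
#' @param domains Optional `domain_table` ([ri_domains()]); never changes the
#'   match set, only the work done.
#' @param edge_labels Convenience toggle forwarded to [match_mode()] when
#'   `mode` is a string.
#' @param timeout Wall-clock budget in seconds (default 180); on expiry the
#'   partial result is returned with `timed_out = TRUE`, not an error.
#' @param limit Optional cap on the number of matches to collect.
#' @param collect Keep the mappings (`TRUE`) or only count them.
#' @return An `ri_matches` object: list with `matches` (integer matrix, one row
#'   per match, column `j` = image of pattern vertex `j-1`), `stats`
#'   (`visited_nodes`, `n_matches`, `elapsed`, `timed_out`), `ordering`, and
#'   the mode. See [tidy.ri_matches()] and [glance.ri_matches()].
#' @examples
#' tri <- labeled_graph(3, rep("A", 3), rbind(c(0,1), c(1,2), c(2,0)), FALSE)
#' k4  <- labeled_graph(4, rep("A", 4), t(utils::combn(0:3, 2)), FALSE)
#' glance(enumerate_matches(tri, k4))   # 24 monomorphisms
#' @export
enumerate_matches <- function(pattern, target, mode = match_mode(),
                              ordering = NULL, domains = NULL,
                              edge_labels = FALSE,
                              timeout = 180, limit = Inf, collect = TRUE) {
  mode <- as_match_mode(mode, edge_labels)
  if (!graph_is_connected(pattern)) stop("pattern must be connected")
  if (is.null(ordering)) ordering <- greatest_constraint_first(pattern)

  n  <- pattern$n_vertices
  nt <- target$n_vertices
  mu <- ordering$mu
  t_start <- proc.time()[["elapsed"]]
  deadline <- t_start + timeout

  st <- new.env(parent = emptyenv())
  st$visited <- 0L
  st$timed_out <- FALSE
  st$found <- list()
  st$n_found <- 0L

  # empty-domain short circuit: some pattern vertex has no compatible target
  dead <- !is.null(domains) && any(lengths(domains) == 0L)

  if (!dead && nt >= 1L) {
    plab <- pattern$vertex_labels; tlab <- target$vertex_labels
    p_out <- lengths(pattern$out_adj); p_in <- lengths(pattern$in_adj)
    t_out <- lengths(target$out_adj); t_in <- lengths(target$in_adj)
    pel <- if (mode$edge_labels) edge_label_map(pattern)
    tel <- if (mode$edge_labels) edge_label_map(target)

    # per level: positions of earlier mu-members joined to this vertex, split
    # by edge direction, plus the pattern edge labels along them
    back_out <- vector("list", n); back_in <- vector("list", n)
    lab_out <- vector("list", n); lab_in <- vector("list", n)
    for (i in seq_len(n)) {
      u <- mu[i]
      earlier <- mu[seq_len(i - 1L)]
      bo <- which(earlier %in% pattern$out_adj[[u + 1L]])
      bi <- which(earlier %in% pattern$in_adj[[u + 1L]])
      back_out[[i]] <- bo; back_in[[i]] <- bi
      if (mode$edge_labels) {
        lab_out[[i]] <- vapply(earlier[bo], function(v) pel[[paste(u, v)]], character(1))
        lab_in[[i]]  <- vapply(earlier[bi], function(v) pel[[paste(v, u)]], character(1))
      }
    }

    M <- rep(NA_integer_, n)        # by level (position in mu)
    used <- logical(nt)

    descend <- function(i) {
      if (st$timed_out || st$n_found >= limit) return()
      u <- mu[i]
      if (i == 1L) {
        cand <- if (!is.null(domains)) domains[[u + 1L]] else 0:(nt - 1L)
      } else {
        par <- ordering$parent[u + 1L]
        pimg <- M[match(par, mu)]
        cand <- graph_neighbors(target, pimg)
        if (!is.null(domains)) cand <- intersect(cand, domains[[u + 1L]])
      }
      for (t in cand) {
        if (st$n_found >= limit) return()
        if (st$visited %% 512L == 0L &&
            proc.time()[["elapsed"]] >= deadline) { st$timed_out <- TRUE; return() }
        st$visited <- st$visited + 1L
        # conditions 1-4, cheapest first
        if (used[t + 1L]) next
        if (plab[u + 1L] != tlab[t + 1L]) next
        if (t_out[t + 1L] < p_out[u + 1L] || t_in[t + 1L] < p_in[u + 1L]) next
        ok <- TRUE
        for (k in seq_along(back_out[[i]])) {
          j <- back_out[[i]][k]; mv <- M[j]
          if (!(mv %in% target$out_adj[[t + 1L]])) { ok <- FALSE; break }
          if (mode$edge_labels &&
              !identical(lab_out[[i]][k], tel[[paste(t, mv)]])) { ok <- FALSE; break }
        }
        if (ok) for (k in seq_along(back_in[[i]])) {
          j <- back_in[[i]][k]; mv <- M[j]
          if (!(mv %in% target$in_adj[[t + 1L]])) { ok <- FALSE; break }
          if (mode$edge_labels &&
              !identical(lab_in[[i]][k], tel[[paste(mv, t)]])) { ok <- FALSE; break }
        }
        if (ok && mode$induced && i > 1L) {
          for (j in seq_len(i - 1L)) {
            mv <- M[j]; v <- mu[j]
            if ((mv %in% target$out_adj[[t + 1L]]) && !has_edge(pattern, u, v)) {
              ok <- FALSE; break }
            if ((mv %in% target$in_adj[[t + 1L]]) && !has_edge(pattern, v, u)) {
              ok <- FALSE; break }
          }
        }
        if (!ok) next
        M[i] <<- t; used[t + 1L] <<- TRUE
        if (i == n) {
          st$n_found <- st$n_found + 1L
          if (collect) {
            m <- integer(n); m[mu + 1L] <- M   # reorder by pattern vertex id
            st$found[[st$n_found]] <- m
          }
        } else {
          descend(i + 1L)
        }
        M[i] <<- NA_integer_; used[t + 1L] <<- FALSE
        if (st$timed_out) return()
      }
    }
    descend(1L)
  }

  elapsed <- proc.time()[["elapsed"]] - t_start
  matches <- if (collect && st$n_found > 0L)
    do.call(rbind, st$found) else matrix(integer(0), ncol = n)
  colnames(matches) <- as.character(0:(n - 1L))
  structure(list(
    matches = matches,
    stats = list(visited_nodes = st$visited, n_matches = st$n_found,
                 elapsed = elapsed, timed_out = st$timed_out),
    ordering = ordering, mode = mode,
    pattern_name = pattern$name, target_name = target$name,
    used_domains = !is.null(domains)),
    class = "ri_matches")
}

#' Count matches without materializing them
#'
#' @inheritParams enumerate_matches
#' @return List with `count` and `stats` (as in [enumerate_matches()]).
#' @export
count_matches <- function(pattern, target, mode = match_mode(), ...) {
  res <- enumerate_matches(pattern, target, mode = mode, collect = FALSE, ...)
  list(count = res$stats$n_matches, stats = res$stats)
}

#' Verify a complete mapping independently of the search
#'
#' Re-checks injectivity, vertex labels, every pattern edge (and label, if
#' requested), and the induced condition directly against the two graphs.
#' Used as a belt-and-braces check on reported matches and on extracted
#' pattern correspondences.
#'
#' @param pattern,target [labeled_graph()]s.
#' @param mapping Integer vector: `mapping[u + 1]` is the 0-based target image
#'   of pattern vertex `u`; must be complete.
#' @param mode A [match_mode()] or mode string.
#' @return Logical scalar.
#' @export
verify_mapping <- function(pattern, target, mapping, mode = match_mode()) {
  mode <- as_match_mode(mode)
  n <- pattern$n_vertices
  mapping <- as.integer(mapping)
  if (length(mapping) != n || anyNA(mapping)) return(FALSE)
  if (any(mapping < 0L) || any(mapping >= target$n_vertices)) return(FALSE)
  if (anyDuplicated(mapping)) return(FALSE)
  if (any(pattern$vertex_labels != target$vertex_labels[mapping + 1L])) return(FALSE)
  pel <- if (mode$edge_labels) edge_label_map(pattern)
  tel <- if (mode$edge_labels) edge_label_map(target)
  em <- pattern$edges
  for (k in seq_len(nrow(em))) {
    a <- mapping[em[k, 1L] + 1L]; b <- mapping[em[k, 2L] + 1L]
    if (!has_edge(target, a, b)) return(FALSE)
    if (mode$edge_labels &&
        !identical(pel[[paste(em[k, 1L], em[k, 2L])]], tel[[paste(a, b)]]))
      return(FALSE)
  }
  if (mode$induced) {
    inv <- rep(NA_integer_, target$n_vertices)
    inv[mapping + 1L] <- 0:(n - 1L)
    tm <- target$edges
    for (k in seq_len(nrow(tm))) {
      pu <- inv[tm[k, 1L] + 1L]; pv <- inv[tm[k, 2L] + 1L]
      if (!is.na(pu) && !is.na(pv) && !has_edge(pattern, pu, pv)) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.ri_matches <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<ri_matches> '%s' in '%s' (%s%s%s)\n", x$pattern_name,
              x$target_name, x$mode$mode,
              if (x$mode$edge_labels) ", edge labels" else "",
              if (x$used_domains) ", initial domains" else ""))
  cat(sprintf("  %d matches, %d visited nodes, %.3fs%s\n", s$n_matches,
              s$visited_nodes, s$elapsed,
              if (s$timed_out) " [TIMED OUT]" else ""))
  invisible(x)
}

#' Tidy and summarize match results
#'
#' `tidy()` returns one row per (match, pattern vertex) pair; `glance()` one
#' row of search statistics.
#'
#' @param x An `ri_matches` or `ri_ordering` object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy ri_matches
#' @export
tidy.ri_matches <- function(x, ...) {
  m <- x$matches
  if (nrow(m) == 0L)
    return(tibble::tibble(match = integer(0), pattern_vertex = integer(0),
                          target_vertex = integer(0)))
  tibble::tibble(
    match = rep(seq_len(nrow(m)), each = ncol(m)),
    pattern_vertex = rep(0:(ncol(m) - 1L), nrow(m)),
    target_vertex = as.integer(t(m)))
}

#' @rdname tidiers
#' @method glance ri_matches
#' @export
glance.ri_matches <- function(x, ...) {
  s <- x$stats
  tibble::tibble(n_matches = s$n_matches, visited_nodes = s$visited_nodes,
                 elapsed = s$elapsed, timed_out = s$timed_out,
                 mode = x$mode$mode, used_domains = x$used_domains)
}
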