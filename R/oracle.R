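#' Brute-force reference enumeration of matches
#'
#' Exhaustively enumerates every injective assignment of pattern vertices to
#' target vertices (in lexicographic order over target tuples) and keeps those
#' satisfying the selected match semantics, checked whole-sale on the complete
#' assignment: vertex labels, every pattern edge, edge labels if enabled, and
#' the induced condition if selected. No ordering, no parents, no domains, no
#' pruning beyond injectivity -- this routine shares none of the search
#' machinery and exists purely as an independent reference for validating the
#' backtracking matcher on small instances.
#'
#' @param pattern [labeled_graph()] with at most 8 vertices.
#' @param target [labeled_graph()] with at most 10 vertices (factorial
#'   blow-up guard).
#' @param mode A [match_mode()] or mode string.
#' @param edge_labels Forwarded to [match_mode()] when `mode` is a string.
#' @return Integer matrix, one row per valid mapping (column `j` = image of
#'   pattern vertex `j-1`), rows in lexicographic order.
#' @export
brute_force_matches <- function(pattern, target, mode = match_mode(),
                                edge_labels = FALSE) {
  mode <- as_match_mode(mode, edge_labels)
  n <- pattern$n_vertices; nt <- target$n_vertices
  if (n > 8L) stop("brute force guard: pattern has more than 8 vertices")
  if (nt > 10L) stop("brute force guard: target has more than 10 vertices")

  found <- list(); nf <- 0L
  if (n >= 1L && n <= nt) {
    asg <- integer(n)
    taken <- logical(nt)
    recurse <- function(pos) {
      if (pos > n) {
        if (valid_assignment(pattern, target, asg, mode)) {
          nf <<- nf + 1L; found[[nf]] <<- asg
        }
        return()
      }
      for (t in 0:(nt - 1L)) {           # ascending: lexicographic output
        if (taken[t + 1L]) next
        asg[pos] <<- t; taken[t + 1L] <<- TRUE
        recurse(pos + 1L)
        taken[t + 1L] <<- FALSE
      }
    }
    recurse(1L)
  }
  out <- if (nf) do.call(rbind, found) else matrix(integer(0), ncol = max(n, 0L))
  colnames(out) <- if (n) as.character(0:(n - 1L))
  out
}

# complete-assignment validity check used only by the brute-force enumerator;
# written directly from the match definitions, not via the search-path checks
valid_assignment <- function(pattern, target, asg, mode) {
  if (any(pattern$vertex_labels != target$vertex_labels[asg + 1L])) return(FALSE)
  em <- pattern$edges
  pel <- if (mode$edge_labels) edge_label_map(pattern)
  tel <- if (mode$edge_labels) edge_label_map(target)
  for (k in seq_len(nrow(em))) {
    a <- asg[em[k, 1L] + 1L]; b <- asg[em[k, 2L] + 1L]
    if (!(b %in% target$out_adj[[a + 1L]])) return(FALSE)
    if (mode$edge_labels &&
        !identical(pel[[paste(em[k, 1L], em[k, 2L])]], tel[[paste(a, b)]]))
      return(FALSE)
  }
  if (mode$induced) {
    for (u in seq_along(asg)) for (v in seq_along(asg)) {
      if (u == v) next
      if ((asg[v] %in% target$out_adj[[asg[u] + 1L]]) &&
          !(  (v - 1L) %in% pattern$out_adj[[u]])) return(FALSE)
    }
  }
  TRUE
}
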