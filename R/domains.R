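#' Initial candidate domains per pattern vertex
#'
#' The initial-domain variant of the matcher precomputes, once, before search,
#' the set of target vertices a priori compatible with each pattern vertex:
#' equal vertex label and in-/out-degree at least the pattern vertex's. No
#' inference or domain reduction ever happens during backtracking -- the whole
#' point of the variant is that this one cheap pass pays off on large dense
#' targets without the cost of constraint propagation.
#'
#' @param pattern,target [labeled_graph()]s.
#' @return A `domain_table`: list of sorted integer vectors, element `u + 1`
#'   holding the 0-based target candidates for pattern vertex `u`.
#' @export
compute_initial_domains <- function(pattern, target) {
  t_out <- lengths(target$out_adj); t_in <- lengths(target$in_adj)
  tlab <- target$vertex_labels
  d <- lapply(seq_len(pattern$n_vertices), function(i) {
    ok <- tlab == pattern$vertex_labels[i] &
      t_out >= length(pattern$out_adj[[i]]) &
      t_in >= length(pattern$in_adj[[i]])
    which(ok) - 1L
  })
  structure(d, class = "domain_table")
}

#' One-pass pattern-edge compatibility filter
#'
#' Sweeps the pattern edges once, in input order: for each pattern edge
#' `(u, v)`, a candidate of `u` with no out-neighbor among `v`'s candidates is
#' dropped, and a candidate of `v` with no in-neighbor among `u`'s candidates
#' is dropped. Domains only ever shrink, and no target vertex that takes part
#' in a true match is ever removed. Deliberately *not* iterated to a fixpoint:
#' repeated propagation would buy smaller domains at the cost this design
#' avoids.
#'
#' @param pattern,target [labeled_graph()]s.
#' @param d A `domain_table` from [compute_initial_domains()].
#' @return The filtered `domain_table` (a subset of `d`, element-wise).
#' @export
filter_edge_compatibility <- function(pattern, target, d) {
  em <- pattern$edges
  for (k in seq_len(nrow(em))) {
    u <- em[k, 1L]; v <- em[k, 2L]
    du <- d[[u + 1L]]; dv <- d[[v + 1L]]
    if (length(du))
      d[[u + 1L]] <- du[vapply(du, function(t)
        any(target$out_adj[[t + 1L]] %in% dv), logical(1))]
    du <- d[[u + 1L]]
    if (length(dv))
      d[[v + 1L]] <- dv[vapply(dv, function(s)
        any(target$in_adj[[s + 1L]] %in% du), logical(1))]
  }
  d
}

#' Compute the full initial-domain table
#'
#' Convenience wrapper: [compute_initial_domains()] followed by one
#' [filter_edge_compatibility()] pass. Pass the result as `domains =` to
#' [enumerate_matches()] to run the initial-domain variant.
#'
#' @inheritParams compute_initial_domains
#' @return A `domain_table`.
#' @examples
#' p <- labeled_graph(2, c("C", "N"), rbind(c(0, 1)), directed = FALSE)
#' ri_domains(p, p)
#' @export
ri_domains <- function(pattern, target) {
  filter_edge_compatibility(pattern, target,
                            compute_initial_domains(pattern, target))
}

#' @export
print.domain_table <- function(x, ...) {
  cat("<domain_table>", length(x), "pattern vertices\n")
  for (i in seq_along(x))
    cat(sprintf("  %d: %s\n", i - 1L,
                if (length(x[[i]])) paste(x[[i]], collapse = " ") else "(empty)"))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy domain_table
#' @export
tidy.domain_table <- function(x, ...) {
  tibble::tibble(pattern_vertex = rep(seq_along(x) - 1L, lengths(x)),
                 target_vertex = as.integer(unlist(x)))
}
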