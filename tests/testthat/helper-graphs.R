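# graph fixtures built in code, plus independent (naive) reference
# implementations used as oracles

make_complete <- function(n, label = "A", directed = FALSE) {
  labeled_graph(n, rep(label, n), if (n >= 2) t(combn(0:(n - 1L), 2L)),
                directed = directed, name = paste0("K", n))
}

make_path <- function(n, label = "A") {
  labeled_graph(n, rep(label, n),
                if (n >= 2) cbind(0:(n - 2L), 1:(n - 1L)),
                directed = FALSE, name = paste0("P", n))
}

make_triangle <- function(labels = rep("A", 3)) {
  labeled_graph(3, labels, rbind(c(0, 1), c(1, 2), c(2, 0)), FALSE, "triangle")
}

# ten-vertex worked example used throughout the ordering tests: vertex 4 has
# the most neighbors; from the prefix (4, 1) the candidates are {0, 2, 5, 6, 7}
# and 5 wins on the look-ahead component despite fewer fresh neighbors
make_ordering_example <- function() {
  labeled_graph(10, rep("A", 10),
                rbind(c(4, 1), c(4, 2), c(4, 6), c(4, 7), c(1, 0), c(1, 5),
                      c(5, 2), c(5, 7), c(5, 8), c(0, 3), c(0, 9)),
                directed = FALSE, name = "ordering_example")
}

# random labeled instance: target + connected extracted pattern
random_instance <- function(seed, n_t = 8L, p = 0.5, n_labels = 2L,
                            directed = FALSE, max_pattern_edges = 3L) {
  withr::with_seed(seed, {
    repeat {
      tseed <- sample.int(1e6, 1L)
      tgt <- random_graph(n_t, p, directed = directed, seed = tseed)
      n_units <- if (directed) nrow(tgt$edges) else nrow(tgt$edges) / 2L
      if (n_units >= 1L) break
    }
    if (n_labels > 1L)
      tgt <- assign_labels(tgt, n_labels, "uniform", seed = sample.int(1e6, 1L))
    spec <- pattern_spec(sample.int(min(max_pattern_edges, n_units), 1L),
                         sample(c("dense", "semidense", "sparse"), 1L),
                         seed = sample.int(1e6, 1L))
    ext <- extract_pattern(tgt, spec)
    list(pattern = ext$pattern, target = tgt, correspondence = ext$correspondence)
  })
}

# canonical row order so match matrices compare as sets
sort_matches <- function(m) {
  m <- unname(as.matrix(m))
  if (nrow(m) <= 1L) return(m)
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

expect_same_match_set <- function(a, b) {
  expect_identical(sort_matches(a), sort_matches(b))
}

# --- naive ordering reference -------------------------------------------------
# recomputes the three candidate sets from scratch at every step by scanning
# the raw edge matrix; shares no code with the production implementation

naive_edges_between <- function(g, a, b) {
  e <- g$edges
  n <- sum((e[, 1] == a & e[, 2] == b) | (e[, 1] == b & e[, 2] == a))
  if (!g$directed) min(n, 1L) else n
}

naive_score <- function(g, prefix, cand) {
  all_v <- 0:(g$n_vertices - 1L)
  outside <- setdiff(all_v, c(prefix, cand))
  w <- function(a, b) naive_edges_between(g, a, b)
  v_vis <- sum(vapply(prefix, function(x) w(cand, x), integer(1)))
  v_neig <- 0L
  for (x in prefix) {
    wit <- outside[vapply(outside, function(j) w(x, j) > 0 && w(cand, j) > 0,
                          logical(1))]
    if (length(wit)) v_neig <- v_neig + max(vapply(wit, function(j) w(cand, j),
                                                   integer(1)))
  }
  v_unv <- 0L
  for (j in outside) {
    if (w(cand, j) > 0 &&
        !any(vapply(prefix, function(x) w(x, j) > 0, logical(1))))
      v_unv <- v_unv + w(cand, j)
  }
  c(v_vis, v_neig, v_unv)
}

naive_gcf_mu <- function(g) {
  n <- g$n_vertices
  ndist <- vapply(0:(n - 1L), function(u)
    sum(vapply(setdiff(0:(n - 1L), u), function(v)
      naive_edges_between(g, u, v) > 0, logical(1))), integer(1))
  mu <- (which(ndist == max(ndist)) - 1L)[1L]
  while (length(mu) < n) {
    cands <- setdiff(0:(n - 1L), mu)
    sc <- t(vapply(cands, function(cc) naive_score(g, mu, cc), integer(3)))
    best <- cands[order(-sc[, 1], -sc[, 2], -sc[, 3], cands)[1L]]
    mu <- c(mu, best)
  }
  mu
}

# a random alternative valid ordering: connected growth from a random start,
# parent = earliest placed neighbor
random_valid_ordering <- function(g, seed) {
  withr::with_seed(seed, {
    n <- g$n_vertices
    mu <- sample.int(n, 1L) - 1L
    while (length(mu) < n) {
      frontier <- setdiff(unique(unlist(lapply(mu, function(u)
        graph_neighbors(g, u)))), mu)
      mu <- c(mu, frontier[sample.int(length(frontier), 1L)])
    }
    parent <- rep(NA_integer_, n)
    for (i in 2:n) {
      nb <- graph_neighbors(g, mu[i])
      parent[mu[i] + 1L] <- mu[which(mu[seq_len(i - 1L)] %in% nb)[1L]]
    }
    structure(list(mu = mu, parent = parent,
                   scores = matrix(0L, n, 3), n_vertices = n,
                   pattern_name = g$name), class = "ri_ordering")
  })
}
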