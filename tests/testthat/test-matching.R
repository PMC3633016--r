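test_that("closed-form symmetry counts: complete patterns in complete targets", {
  for (n in 1:4) for (m in n:7) {
    res <- count_matches(make_complete(n), make_complete(m))
    expect_equal(res$count, prod(seq(m, m - n + 1L)),
                 info = sprintf("K%d in K%d", n, m))
  }
})

test_that("path-in-clique counts separate the two match semantics", {
  p3 <- make_path(3); k3 <- make_complete(3); k4 <- make_complete(4)
  expect_equal(count_matches(p3, k3, "monomorphism")$count, 6L)
  expect_equal(count_matches(p3, k3, "induced")$count, 0L)
  expect_equal(count_matches(make_triangle(), k4)$count, 24L)
})

test_that("degenerate instances behave", {
  one <- labeled_graph(1, "C")
  expect_equal(count_matches(one, one)$count, 1L)
  # no edges in the target: any pattern with an edge cannot match
  edgeless <- labeled_graph(5, rep("A", 5))
  expect_equal(count_matches(make_path(2), edgeless)$count, 0L)
  # label absent from the target kills level 0 within |V'| checks
  np <- labeled_graph(1, "N")
  ct <- labeled_graph(4, rep("C", 4), t(combn(0:3, 2)), FALSE)
  res <- count_matches(np, ct)
  expect_equal(res$count, 0L)
  expect_lte(res$stats$visited_nodes, ct$n_vertices)
  # pattern larger than target
  expect_equal(count_matches(make_complete(4), make_complete(3))$count, 0L)
  expect_error(enumerate_matches(
    labeled_graph(4, rep("A", 4), rbind(c(0, 1), c(2, 3)), FALSE),
    make_complete(4)), "connected")
})

test_that("feasibility conditions fire in their fixed order", {
  pat <- labeled_graph(2, c("N", "N"), rbind(c(0, 1)), directed = TRUE)
  tgt <- labeled_graph(3, c("N", "C", "N"), rbind(c(0, 2), c(2, 0)), TRUE)
  partial <- rep(NA_integer_, 2)
  # condition 1: target vertex already used
  p1 <- partial; p1[2L] <- 0L
  expect_false(is_feasible(pat, tgt, p1, 0, 0))
  # condition 2: label mismatch
  expect_false(is_feasible(pat, tgt, partial, 0, 1))
  # condition 3: pattern out-degree exceeds the target vertex's
  fan <- labeled_graph(4, rep("A", 4), rbind(c(0, 1), c(0, 2), c(0, 3)), TRUE)
  thin <- labeled_graph(4, rep("A", 4), rbind(c(0, 1), c(0, 2)), TRUE)
  expect_false(is_feasible(fan, thin, rep(NA_integer_, 4), 0, 0))
  # condition 4: mapped pattern edge missing in the target
  p4 <- partial; p4[1L] <- 1L   # pattern 0 -> target 1 (isolated from 0<->2)
  expect_false(is_feasible(pat, tgt, p4, 1, 0))
  # and the happy path
  p5 <- partial; p5[1L] <- 0L
  expect_true(is_feasible(pat, tgt, p5, 1, 2))
  # induced mode rejects the extra target edge between endpoint images:
  # with path endpoint 0 already on target 0, placing endpoint 2 on the
  # adjacent target 1 creates an unmirrored target edge
  p3 <- make_path(3); k3 <- make_complete(3)
  pp <- c(0L, NA_integer_, NA_integer_)
  expect_false(is_feasible(p3, k3, pp, 2, 1, "induced"))
  expect_true(is_feasible(p3, k3, pp, 2, 1, "monomorphism"))
  expect_error(is_feasible(p3, k3, c(0L, 1L, NA), 0, 2), "already assigned")
})

test_that("candidate targets come from the parent's image neighborhood", {
  p3 <- make_path(3); k3 <- make_complete(3)
  ord <- greatest_constraint_first(p3)   # mu = (1, 0, 2)
  partial <- rep(NA_integer_, 3)
  expect_equal(candidate_targets(k3, ord, partial, 0), 0:2)
  partial[2L] <- 0L                       # M(1) = 0
  expect_equal(candidate_targets(k3, ord, partial, 1), c(1L, 2L))
  # parent mapped onto an isolated target vertex: no candidates
  tgt <- labeled_graph(3, rep("A", 3), rbind(c(1, 2)), FALSE)
  partial2 <- c(NA, 0L, NA)
  expect_equal(candidate_targets(tgt, ord, partial2, 1), integer(0))
})

test_that("matcher equals the brute-force reference on random instances", {
  for (seed in 1:60) {
    inst <- random_instance(seed, n_t = sample(4:8, 1L),
                            p = sample(c(0.2, 0.5, 0.8), 1L),
                            n_labels = sample(1:3, 1L),
                            directed = seed %% 2L == 0L)
    for (mode in c("monomorphism", "induced")) {
      got <- enumerate_matches(inst$pattern, inst$target, mode)
      want <- brute_force_matches(inst$pattern, inst$target, mode)
      expect_same_match_set(got$matches, want)
      # belt and braces: every reported mapping re-verifies from scratch
      for (r in seq_len(nrow(got$matches)))
        expect_true(verify_mapping(inst$pattern, inst$target,
                                   got$matches[r, ], mode))
    }
  }
})

test_that("induced matches are a subset of monomorphisms", {
  for (seed in 101:120) {
    inst <- random_instance(seed, n_t = 7L, p = 0.6, n_labels = 2L)
    mono <- sort_matches(enumerate_matches(inst$pattern, inst$target)$matches)
    ind <- sort_matches(enumerate_matches(inst$pattern, inst$target,
                                          "induced")$matches)
    key <- function(m) apply(m, 1L, paste, collapse = ",")
    expect_true(all(key(ind) %in% key(mono)))
  }
})

test_that("the match set does not depend on the variable ordering", {
  for (seed in 201:215) {
    inst <- random_instance(seed, n_t = 7L, p = 0.5, n_labels = 2L)
    ref <- enumerate_matches(inst$pattern, inst$target)
    alt_ord <- random_valid_ordering(inst$pattern, seed)
    alt <- enumerate_matches(inst$pattern, inst$target, ordering = alt_ord)
    expect_same_match_set(ref$matches, alt$matches)
  }
})

test_that("edge-label checking constrains matches and agrees with brute force", {
  pat <- labeled_graph(2, c("C", "C"), rbind(c(0, 1)), directed = TRUE,
                       edge_labels = "double")
  tgt <- labeled_graph(3, rep("C", 3), rbind(c(0, 1), c(1, 2)), TRUE,
                       edge_labels = c("double", "single"))
  with_lab <- enumerate_matches(pat, tgt, match_mode(edge_labels = TRUE))
  without <- enumerate_matches(pat, tgt)
  expect_equal(with_lab$stats$n_matches, 1L)
  expect_equal(without$stats$n_matches, 2L)
  expect_same_match_set(with_lab$matches,
                        brute_force_matches(pat, tgt, match_mode(edge_labels = TRUE)))
})

test_that("limit and timeout stop the search gracefully", {
  tri <- make_triangle(); k5 <- make_complete(5)
  lim <- enumerate_matches(tri, k5, limit = 7)
  expect_equal(lim$stats$n_matches, 7L)
  expect_false(lim$stats$timed_out)
  out <- enumerate_matches(tri, k5, timeout = 0)
  expect_true(out$stats$timed_out)
  expect_equal(out$stats$visited_nodes, 0L)
})

test_that("visited nodes bound match counts and stats are well-formed", {
  for (seed in 301:310) {
    inst <- random_instance(seed, n_t = 8L, p = 0.5, n_labels = 1L)
    g <- glance(enumerate_matches(inst$pattern, inst$target))
    expect_lte(g$n_matches, g$visited_nodes)
    expect_gte(g$visited_nodes, 0L)
    expect_false(g$timed_out)
  }
})

test_that("tidy() gives one row per matched vertex pair", {
  res <- enumerate_matches(make_triangle(), make_complete(4))
  tt <- tidy(res)
  expect_equal(nrow(tt), 24L * 3L)
  expect_named(tt, c("match", "pattern_vertex", "target_vertex"))
  empty <- enumerate_matches(make_complete(4), make_complete(3))
  expect_equal(nrow(tidy(empty)), 0L)
})

test_that("counts agree with igraph's independent matcher on unlabeled graphs", {
  for (seed in 401:406) {
    inst <- random_instance(seed, n_t = 8L, p = 0.5, n_labels = 1L)
    ours <- count_matches(inst$pattern, inst$target)$count
    ig_n <- igraph::count_subgraph_isomorphisms(
      as_igraph(inst$pattern), as_igraph(inst$target),
      method = "lad", induced = FALSE)
    expect_equal(ours, as.integer(ig_n))
  }
})
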