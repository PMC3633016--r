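test_that("uniform random graphs hit their edge-probability contract", {
  expect_equal(nrow(random_graph(10, 0, seed = 1)$edges), 0L)
  k4 <- random_graph(4, 1, seed = 1)
  expect_equal(nrow(k4$edges), 12L)       # complete, symmetric arcs
  expect_error(random_graph(5, 1.5), "probability")
  # reproducibility
  expect_identical(random_graph(30, 0.2, seed = 9)$edges,
                   random_graph(30, 0.2, seed = 9)$edges)
  # binomial expectation over seeds: mean undirected edge count near p*C(n,2)
  n <- 30L; p <- 0.15; reps <- 200L
  counts <- vapply(seq_len(reps), function(s)
    nrow(random_graph(n, p, seed = s)$edges) / 2L, numeric(1))
  mu <- p * choose(n, 2)
  se <- sqrt(choose(n, 2) * p * (1 - p) / reps)
  expect_lt(abs(mean(counts) - mu), 4 * se)
})

test_that("mesh graphs satisfy the lattice edge-count formula", {
  sq <- mesh_graph(c(2, 2))
  expect_equal(sq$n_vertices, 4L)
  expect_equal(nrow(sq$edges) / 2L, 4L)
  cube <- mesh_graph(c(2, 2, 2))
  expect_equal(cube$n_vertices, 8L)
  expect_equal(nrow(cube$edges) / 2L, 12L)
  for (dims in list(c(3, 5), c(2, 3, 4), c(2, 2, 3, 2))) {
    g <- mesh_graph(dims)
    want <- sum(vapply(seq_along(dims), function(d)
      (dims[d] - 1L) * prod(dims[-d]), numeric(1)))
    expect_equal(nrow(g$edges) / 2L, want)
    expect_true(graph_is_connected(g))
    # lattice degrees never exceed two per dimension
    expect_lte(max(graph_degrees(g)$n_neighbors), 2L * length(dims))
  }
  expect_error(mesh_graph(5), "dimensionality")
  expect_error(mesh_graph(c(2, 2, 2, 2, 2)), "dimensionality")
  expect_error(mesh_graph(c(1, 3)), "at least 2")
})

test_that("bounded-valence graphs are connected and exactly regular", {
  k4 <- bounded_valence_graph(4, 3, seed = 1)
  expect_equal(sort_matches(k4$edges), sort_matches(make_complete(4)$edges))
  for (val in c(3L, 6L)) {
    g <- bounded_valence_graph(20, val, seed = 42)
    expect_true(all(graph_degrees(g)$n_neighbors == val))
    expect_true(graph_is_connected(g))
  }
  expect_identical(bounded_valence_graph(20, 3, seed = 5)$edges,
                   bounded_valence_graph(20, 3, seed = 5)$edges)
  expect_error(bounded_valence_graph(5, 3), "even")
  expect_error(bounded_valence_graph(4, 5), "n > valence")
})

test_that("label assignment follows the requested distribution", {
  g <- random_graph(3200, 0.001, seed = 2)
  one <- assign_labels(g, 1, "uniform", seed = 1)
  expect_length(unique(one$vertex_labels), 1L)

  uniq <- assign_labels(g, 0, "unique")
  expect_equal(anyDuplicated(uniq$vertex_labels), 0L)
  expect_length(unique(uniq$vertex_labels), g$n_vertices)

  # uniform over 32 symbols on 3200 vertices: every frequency near 100
  unif <- assign_labels(g, 32, "uniform", seed = 3)
  freq <- table(unif$vertex_labels)
  expect_length(freq, 32L)
  se <- sqrt(3200 * (1 / 32) * (31 / 32))
  expect_true(all(abs(freq - 100) < 4 * se))

  # discretized gaussian: center label beats the extreme ones
  norm <- assign_labels(g, 9, "normal", seed = 4)
  nf <- table(factor(norm$vertex_labels, levels = sprintf("L%d", 1:9)))
  expect_gt(nf[["L5"]], nf[["L1"]])
  expect_gt(nf[["L5"]], nf[["L9"]])
  expect_error(assign_labels(g, 0, "uniform"), "n_labels")
})

test_that("extracted patterns are connected verified subgraphs", {
  tgt <- assign_labels(random_graph(40, 0.3, seed = 21), 3, "uniform", seed = 22)
  for (seed in 1:15) {
    ext <- extract_pattern(tgt, pattern_spec(sample(2:10, 1L),
                                             sample(c("dense", "semidense", "sparse"), 1L),
                                             seed = seed))
    expect_true(graph_is_connected(ext$pattern))
    # the returned correspondence is itself a monomorphism...
    expect_true(verify_mapping(ext$pattern, tgt, ext$correspondence))
    # ...and the matcher finds it among the matches
    res <- enumerate_matches(ext$pattern, tgt, limit = Inf, timeout = 30)
    key <- apply(res$matches, 1L, paste, collapse = ",")
    expect_true(paste(ext$correspondence, collapse = ",") %in% key)
  }
})

test_that("requesting every edge of a connected target returns it whole", {
  tgt <- mesh_graph(c(3, 3))
  ext <- extract_pattern(tgt, pattern_spec(12, "sparse", seed = 1))
  expect_equal(ext$pattern$n_vertices, 9L)
  expect_equal(nrow(ext$pattern$edges), nrow(tgt$edges))
  expect_equal(ext$correspondence, 0:8)
  expect_error(extract_pattern(tgt, pattern_spec(13, "sparse", seed = 1)),
               "only 12 edges")
})

test_that("density classes order the vertex/edge ratio as dense < semidense < sparse", {
  tgt <- random_graph(90, 0.5, seed = 31)
  ratio <- function(cls) {
    mean(vapply(1:25, function(s) {
      p <- extract_pattern(tgt, pattern_spec(32, cls, seed = s))$pattern
      p$n_vertices / (nrow(p$edges) / 2L)
    }, numeric(1)))
  }
  r <- vapply(c("dense", "semidense", "sparse"), ratio, numeric(1))
  expect_lt(r[["dense"]], r[["semidense"]])
  expect_lt(r[["semidense"]], r[["sparse"]])
})

test_that("generators are pure functions of their seed", {
  a <- extract_pattern(random_graph(50, 0.2, seed = 8),
                       pattern_spec(10, "semidense", seed = 9))
  b <- extract_pattern(random_graph(50, 0.2, seed = 8),
                       pattern_spec(10, "semidense", seed = 9))
  expect_identical(a$pattern$edges, b$pattern$edges)
  expect_identical(a$correspondence, b$correspondence)
})
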