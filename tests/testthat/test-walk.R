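test_that("multigraph merge reproduces the worked-example probabilities exactly", {
  M <- merge_transition(toy_multigraph())
  # g1 belongs to layers 1 and 2: 1/2 * 1/2 + 1/2 * 1
  expect_equal(M["g1", "g2"], 0.75)
  # g2 belongs to all three layers with degrees 2, 3, 2
  expect_equal(M["g2", "g3"], 4 / 9)
  expect_equal(layer_counts(toy_multigraph()),
               c(g1 = 2L, g2 = 3L, g3 = 3L, g4 = 2L))
})

test_that("a single-layer multigraph merges to the layer's own transition matrix", {
  net <- random_network(8, seed = 21)
  mg <- gene_multigraph(list(only = net))
  expect_equal(merge_transition(mg), transition_from_network(net))
})

test_that("merged rows sum to one on random multigraphs", {
  for (seed in 22:26) {
    mg <- random_multigraph(sample(5:15, 1), n_layers = sample(2:4, 1), seed = seed)
    M <- merge_transition(mg)
    expect_lt(max(abs(rowSums(M) - 1)), 1e-9)
    expect_true(all(M >= 0))
  }
})

test_that("multigraph construction rejects uncovered nodes and bad layer weights", {
  net <- random_network(5, seed = 30)
  expect_error(gene_multigraph(list(net), universe = c(net$node_ids, "zz")),
               "N_i = 0")
  # two disjoint-coverage layers cannot both get weight 0.6/0.4 per node
  l1 <- weighted_network(data.frame(from = "a", to = "b"))
  l2 <- weighted_network(data.frame(from = "b", to = "c"))
  expect_error(gene_multigraph(list(l1, l2), layer_weights = c(0.6, 0.4)),
               "sum to 1")
  # weights that do sum to 1 on every node are accepted
  l3 <- weighted_network(data.frame(from = c("a", "b"), to = c("b", "c")))
  mg <- gene_multigraph(list(l3, l3), layer_weights = c(0.6, 0.4))
  expect_equal(merge_transition(mg), transition_from_network(l3))
})

test_that("restart probability one pins the walker to the initial vector", {
  M <- merge_transition(toy_multigraph())
  p0 <- initial_distribution(rownames(M), c("g1", "g4"))
  res <- rwr(M, p0, walk_config(gamma = 1))
  expect_equal(res$p, p0)
})

test_that("iterative walk matches the dense linear-solve oracle", {
  for (seed in 31:36) {
    set.seed(seed)
    n <- sample(5:50, 1)
    gamma <- stats::runif(1, 0.1, 0.9)
    M <- transition_from_network(random_network(n))
    seeds <- sample(rownames(M), sample(1:3, 1))
    p0 <- initial_distribution(rownames(M), seeds)
    res <- rwr(M, p0, walk_config(gamma = gamma))
    expect_lt(max(abs(res$p - solve_stationary(M, p0, gamma))), 1e-8)
  }
})

test_that("walk agrees with igraph's personalized PageRank on a weighted graph", {
  skip_if_not_installed("igraph")
  net <- random_network(20, seed = 40)
  M <- transition_from_network(net)
  p0 <- initial_distribution(net$node_ids, c("n03", "n11"))
  gamma <- 0.7
  ours <- rwr(M, p0, walk_config(gamma = gamma))$p
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$node_ids)
  pr <- igraph::page_rank(g, damping = 1 - gamma, personalized = p0,
                          weights = igraph::E(g)$weight)$vector
  expect_lt(max(abs(ours - pr[names(ours)])), 1e-7)
})

test_that("the walk conserves probability and contracts monotonically", {
  for (seed in 41:43) {
    set.seed(seed)
    M <- merge_transition(random_multigraph(12, seed = seed))
    p0 <- initial_distribution(rownames(M), sample(rownames(M), 2))
    res <- rwr(M, p0, walk_config(gamma = 0.3), keep_trace = TRUE)
    expect_true(all(abs(res$trace$total_mass - 1) <= 1e-9))
    expect_true(all(diff(res$trace$residual) <= 1e-12))
  }
})

test_that("non-convergence raises a typed error reporting the residual", {
  M <- merge_transition(toy_multigraph())
  p0 <- initial_distribution(rownames(M), "g4")
  expect_error(rwr(M, p0, walk_config(gamma = 0.1, tol = 1e-14, max_iter = 2L)),
               class = "multiwalk_no_convergence")
})

test_that("stationary entries of the worked five-gene matrix round as printed", {
  M <- toy_merged_matrix()
  p0 <- initial_distribution(rownames(M), "g4")
  p <- rwr(M, p0, walk_config(gamma = 0.7))$p
  expect_equal(round(unname(p[c("g1", "g2", "g3", "g4")]), 2),
               c(0.01, 0.04, 0.13, 0.71))
  # g3 is the best-ranked non-seed
  ranking <- multiwalk:::rank_candidates(p[c("g1", "g2", "g3", "g5")])
  expect_equal(ranking$gene[1], "g3")
})

test_that("prioritize ranks candidates deterministically with identifier tie-breaks", {
  mg <- toy_multigraph()
  ranking <- prioritize(mg, seeds = "g4", candidates = c("g1", "g2", "g3"))
  expect_equal(ranking$gene[1], "g2")  # g4's only edges lead through g2
  expect_equal(ranking$rank, 1:3)
  # a single candidate is rank 1 whatever its score
  one <- prioritize(mg, seeds = "g4", candidates = "g1")
  expect_equal(one$rank, 1L)
  # exact ties fall back to ascending identifier
  r <- multiwalk:::rank_candidates(c(b = 0.2, a = 0.2, c = 0.5))
  expect_equal(r$gene, c("c", "a", "b"))
  expect_error(prioritize(mg, seeds = "gX", candidates = "g1"), "gX")
  expect_error(prioritize(mg, seeds = "g4", candidates = c("g1", "g4")),
               "disjoint")
})

test_that("rankings are equivariant under node relabelling", {
  mg <- random_multigraph(10, seed = 50)
  relabel <- stats::setNames(sprintf("z%02d", sample(10)), mg$universe)
  rename_net <- function(net) {
    weighted_network(data.frame(from = unname(relabel[net$edges$from]),
                                to = unname(relabel[net$edges$to]),
                                weight = net$edges$weight,
                                stringsAsFactors = FALSE))
  }
  mg2 <- gene_multigraph(lapply(mg$layers, rename_net))
  seeds <- mg$universe[1:2]
  cands <- mg$universe[5:9]
  r1 <- prioritize(mg, seeds, cands)
  r2 <- prioritize(mg2, unname(relabel[seeds]), unname(relabel[cands]))
  expect_equal(unname(relabel[r1$gene]), r2$gene)
  expect_equal(r1$score, r2$score, tolerance = 1e-12)
})
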