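make_positions <- function(genes, chrom = "chr1", spacing = 10) {
  data.frame(gene = genes, chrom = chrom,
             start = seq_along(genes) * spacing,
             end = seq_along(genes) * spacing + spacing / 2,
             stringsAsFactors = FALSE)
}

test_that("linkage interval picks the n nearest same-chromosome genes", {
  genes <- sprintf("g%03d", 1:200)
  pos <- make_positions(genes)
  expect_setequal(linkage_interval("g050", pos, n = 4),
                  c("g050", "g048", "g049", "g051", "g052"))
  # matches a brute-force midpoint-distance sort on scrambled positions
  set.seed(7)
  pos2 <- pos
  pos2$start <- sample(1000, 200) * 10
  pos2$end <- pos2$start + 3
  held <- "g117"
  mid <- (pos2$start + pos2$end) / 2
  names(mid) <- pos2$gene
  d <- abs(mid - mid[held])
  oracle <- names(sort(d[names(d) != held]))[1:99]
  expect_setequal(linkage_interval(held, pos2), c(held, oracle))
  expect_length(linkage_interval(held, pos2), 100)
})

test_that("short chromosomes are taken whole with a warning", {
  pos <- make_positions(sprintf("g%03d", 1:100))
  expect_setequal(suppressWarnings(linkage_interval("g001", pos, n = 99)),
                  pos$gene)  # exactly 100 genes: forced
  small <- make_positions(c("a", "b", "c"))
  expect_warning(got <- linkage_interval("b", small, n = 99), "only 2 other")
  expect_setequal(got, c("a", "b", "c"))
  expect_error(linkage_interval("zz", small), "not in position table")
})

test_that("cross-validation produces one trial per disease gene", {
  mg <- random_multigraph(30, seed = 70)
  genes <- mg$universe
  pos <- make_positions(genes)
  sets <- list(d1 = genes[1:6], d2 = genes[7:13], d3 = genes[14:21])
  res <- suppressWarnings(loocv_rwrm(sets, mg, pos, interval_size = 10))
  expect_equal(nrow(res$trials), 21L)  # 6 + 7 + 8 held-out rounds
  expect_true(all(res$trials$rank >= 1 &
                    res$trials$rank <= res$trials$n_candidates))
  # deterministic: identical inputs give identical trials
  res2 <- suppressWarnings(loocv_rwrm(sets, mg, pos, interval_size = 10))
  expect_identical(res$trials, res2$trials)
  # diseases below two usable genes are skipped, unknown genes dropped
  res3 <- suppressWarnings(
    loocv_rwrm(c(sets, list(tiny = genes[1], ghost = c("zz", "yy"))),
               mg, pos, interval_size = 10))
  expect_equal(nrow(res3$trials), 21L)
})

test_that("rank-based AUC matches closed forms and the pairwise oracle", {
  perfect <- make_loocv(data.frame(disease = "d", gene = letters[1:5],
                                   n_candidates = 50L, rank = 1L,
                                   success = TRUE))
  expect_equal(rank_auc(perfect)$overall_auc, 1)
  worst <- make_loocv(data.frame(disease = "d", gene = letters[1:5],
                                 n_candidates = 50L, rank = 50L,
                                 success = FALSE))
  expect_equal(rank_auc(worst)$overall_auc, 0)
  # pairwise Mann-Whitney count on small instances
  set.seed(8)
  for (i in 1:5) {
    n <- sample(5:30, 1)
    ranks <- sample(n, sample(3:20, 1), replace = TRUE)
    res <- make_loocv(data.frame(disease = "d", gene = as.character(seq_along(ranks)),
                                 n_candidates = n, rank = ranks,
                                 success = ranks == 1L))
    expect_equal(rank_auc(res)$overall_auc,
                 brute_auc(ranks, rep(n, length(ranks))),
                 tolerance = 1e-12)
  }
  # uniform random ranks hover around one half
  set.seed(9)
  ranks <- sample(100, 500, replace = TRUE)
  unif <- make_loocv(data.frame(disease = rep(c("d1", "d2"), 250),
                                gene = as.character(1:500),
                                n_candidates = 100L, rank = ranks,
                                success = ranks == 1L))
  a <- rank_auc(unif)
  expect_gt(a$overall_auc, 0.47)
  expect_lt(a$overall_auc, 0.53)
  # ROC endpoints
  expect_equal(a$roc$tpr[1], 0)
  expect_equal(a$roc$tpr[nrow(a$roc)], 1)
  expect_equal(a$roc$fpr[nrow(a$roc)], 1)
  # degenerate single-candidate trials are excluded with a warning
  mixed <- make_loocv(data.frame(disease = "d", gene = c("a", "b"),
                                 n_candidates = c(1L, 10L), rank = c(1L, 1L),
                                 success = TRUE))
  expect_warning(am <- rank_auc(mixed), "single-candidate")
  expect_equal(am$n_trials, 1L)
})

test_that("strict rank-1 success never exceeds rank-1 trials", {
  bench <- generate_benchmark(synthetic_spec(
    n_genes = 80L, n_modules = 4L, module_size = 6L, n_phenotypes = 8L,
    n_chromosomes = 1L, rng_seed = 77L))
  res <- suppressWarnings(loocv_rwrm(bench$disease_sets, bench$multigraph,
                                     bench$positions, interval_size = 20L))
  expect_lte(res$success_count, sum(res$trials$rank == 1L))
  expect_true(all(!res$trials$success | res$trials$rank == 1L))
})

test_that("heterogeneous cross-validation counts strict top-rank successes", {
  bench <- generate_benchmark(synthetic_spec(
    n_genes = 60L, n_modules = 3L, module_size = 6L, n_phenotypes = 6L,
    pgr_per_module = 2L, n_chromosomes = 1L, rng_seed = 78L))
  phen <- build_knn_graph(bench$phenotype_similarity, 2)
  h <- heterogeneous_network(bench$multigraph, phen, bench$associations,
                             lambda = 0.5)
  res <- suppressWarnings(loocv_chn(h, bench$positions, interval_size = 15L))
  expect_equal(nrow(res$trials), sum(bench$associations$B))
  expect_equal(res$success_count, sum(res$trials$success))

  # shuffling input row order changes nothing
  set.seed(1)
  pos2 <- bench$positions[sample(nrow(bench$positions)), ]
  res2 <- suppressWarnings(loocv_chn(h, pos2, interval_size = 15L))
  expect_equal(res$success_count, res2$success_count)
  expect_equal(sort(res$trials$rank), sort(res2$trials$rank))

  # jumping probability changes the outcome; both runs are reproducible
  h0 <- heterogeneous_network(bench$multigraph, phen, bench$associations,
                              lambda = 0)
  res0 <- suppressWarnings(loocv_chn(h0, bench$positions, interval_size = 15L))
  expect_identical(res0$trials,
                   suppressWarnings(loocv_chn(h0, bench$positions,
                                              interval_size = 15L))$trials)
  expect_false(identical(res0$trials$rank, res$trials$rank))
})

test_that("a single-candidate interval is a success by definition", {
  # two genes alone on their chromosome: the interval around gA is {gA, gB},
  # and with gB a seed it shrinks to the held-out gene alone
  mg <- gene_multigraph(list(weighted_network(
    data.frame(from = c("gA", "gB", "gC"), to = c("gB", "gC", "gA")))))
  pos <- make_positions(c("gA", "gB"))
  phen <- weighted_network(data.frame(from = "P1", to = "P2"))
  at <- association_table(data.frame(gene = c("gA", "gB"),
                                     phenotype = c("P1", "P1")),
                          phenotype_ids = phen$node_ids)
  h <- heterogeneous_network(mg, phen, at, lambda = 0.5)
  res <- suppressWarnings(loocv_chn(h, pos, interval_size = 99L))
  expect_true(all(res$trials$n_candidates == 1L))
  expect_equal(res$success_count, 2L)
})

test_that("the K sweep tabulates one cross-validation per K", {
  bench <- generate_benchmark(synthetic_spec(
    n_genes = 60L, n_modules = 3L, module_size = 6L, n_phenotypes = 6L,
    pgr_per_module = 2L, n_chromosomes = 1L, rng_seed = 79L))
  tab <- suppressWarnings(k_sweep(c(2L, 4L), bench$phenotype_similarity,
                                  bench$multigraph, bench$associations,
                                  bench$positions, interval_size = 15L))
  expect_equal(tab$k, c(2L, 4L))
  phen <- build_knn_graph(bench$phenotype_similarity, 2)
  h <- heterogeneous_network(bench$multigraph, phen, bench$associations)
  direct <- suppressWarnings(loocv_chn(h, bench$positions, interval_size = 15L))
  expect_equal(tab$success_count[1], direct$success_count)
  expect_error(
    suppressWarnings(k_sweep(6L, bench$phenotype_similarity, bench$multigraph,
                             bench$associations, bench$positions,
                             interval_size = 15L)),
    "K = 6")
})
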