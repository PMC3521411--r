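# Shared generators and independent oracles for the property tests.

# Random connected-enough weighted network: a chain backbone guarantees
# every node an edge, plus random extra edges.
random_network <- function(n, extra = n, seed = NULL, weights = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  from <- ids[seq_len(n - 1)]
  to <- ids[2:n]
  if (extra > 0) {
    pool <- t(combn(ids, 2))
    chain <- paste(from, to)
    pool <- pool[!(paste(pool[, 1], pool[, 2]) %in% chain), , drop = FALSE]
    take <- sample(nrow(pool), min(extra, nrow(pool)))
    from <- c(from, pool[take, 1])
    to <- c(to, pool[take, 2])
  }
  w <- if (weights) stats::runif(length(from), 0.1, 2) else rep(1, length(from))
  weighted_network(data.frame(from = from, to = to, weight = w,
                              stringsAsFactors = FALSE))
}

random_multigraph <- function(n, n_layers = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  layers <- lapply(seq_len(n_layers), function(k) random_network(n, extra = n))
  gene_multigraph(layers)
}

random_similarity <- function(n, seed = NULL, zero_frac = 0) {
  if (!is.null(seed)) set.seed(seed)
  ids <- letters[seq_len(n)]
  s <- matrix(stats::runif(n * n), n, n, dimnames = list(ids, ids))
  if (zero_frac > 0) s[stats::runif(n * n) < zero_frac] <- 0
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

# Exhaustive per-column top-k selection, independent of build_knn_graph.
brute_knn_edges <- function(sim, k) {
  ids <- rownames(sim)
  out <- character(0)
  for (i in seq_along(ids)) {
    s <- sim[, i]
    s[i] <- -Inf
    cand <- ids[s > 0]
    cand <- cand[order(-s[cand], cand)]
    for (nb in head(cand, k)) {
      out <- c(out, paste(min(ids[i], nb), max(ids[i], nb)))
    }
  }
  sort(unique(out))
}

# Closed-form stationary distribution: p = gamma * (I - (1-gamma) M^T)^-1 p0.
solve_stationary <- function(M, p0, gamma) {
  n <- nrow(M)
  p <- gamma * solve(diag(n) - (1 - gamma) * t(M), p0)
  stats::setNames(as.numeric(p), rownames(M))
}

# Pairwise Mann-Whitney AUC: each trial contributes one positive at rank r
# among n candidates; count positive-beats-negative pairs explicitly.
brute_auc <- function(ranks, n_candidates) {
  wins <- 0
  pairs <- 0
  for (t in seq_along(ranks)) {
    wins <- wins + (n_candidates[t] - ranks[t])
    pairs <- pairs + (n_candidates[t] - 1)
  }
  # pooled mean of per-trial fractions (all trials share n in the tests)
  mean((n_candidates - ranks) / (n_candidates - 1))
}

make_loocv <- function(trials, protocol = "rwrm") {
  multiwalk:::new_loocv_result(trials, protocol)
}
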