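#' Random-walk configuration
#'
#' @param gamma restart probability in (0, 1]; at every step the walker
#'   returns to the initial distribution with probability `gamma`
#' @param tol L1 convergence tolerance on successive iterates
#' @param max_iter maximum number of iterations before giving up
#' @return list of class `walk_config`
#' @export
walk_config <- function(gamma = 0.7, tol = 1e-10, max_iter = 10000L) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 || gamma > 1) {
    stop("`gamma` must be a single number in (0, 1]")
  }
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) stop("`tol` must be > 0")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("`max_iter` must be a positive integer")
  structure(list(gamma = gamma, tol = tol, max_iter = max_iter),
            class = "walk_config")
}

#' Initial probability vector over a seed set
#'
#' Assigns equal probability to every seed node, summing to one; all other
#' nodes start at zero.
#'
#' @param node_ids ordered identifiers of the walked graph
#' @param seeds non-empty subset of `node_ids`
#' @return named numeric vector in `node_ids` order
#' @export
initial_distribution <- function(node_ids, seeds) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("seed set is empty")
  missing <- setdiff(seeds, node_ids)
  if (length(missing)) {
    stop("seed node(s) not in the network: ", paste(missing, collapse = ", "))
  }
  p0 <- stats::setNames(numeric(length(node_ids)), node_ids)
  p0[seeds] <- 1 / length(seeds)
  p0
}

# Error condition used by the CLI to map non-convergence to exit code 3.
no_convergence_error <- function(iterations, residual) {
  stop(structure(
    class = c("multiwalk_no_convergence", "error", "condition"),
    list(message = sprintf(
      "random walk did not converge within %d iterations (final L1 residual %.3g)",
      iterations, residual),
      call = NULL)
  ))
}

#' Random walk with restart
#'
#' Iterates `p <- (1 - gamma) * t(M) %*% p + gamma * p0` from `p0` until the
#' L1 change between successive iterates falls below `cfg$tol`. The
#' stationary vector scores every node by its proximity to the seed set:
#' the walker diffuses along edges but restarts at the seeds with
#' probability `gamma` each step, so mass concentrates near them.
#'
#' @param M row-stochastic transition matrix (row = from)
#' @param p0 initial probability vector in the row order of `M`, summing
#'   to 1 (see [initial_distribution()])
#' @param cfg a [walk_config()]
#' @param keep_trace record per-iteration diagnostics (L1 residual and
#'   total probability mass) in a `trace` data frame on the result
#' @return object of class `stationary_result`: list with `p` (named
#'   stationary vector), `iterations` and `residual` (and `trace` when
#'   requested)
#' @export
rwr <- function(M, p0, cfg = walk_config(), keep_trace = FALSE) {
  stopifnot(inherits(cfg, "walk_config"))
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("`M` must be a square matrix")
  validate_transition(M)
  if (length(p0) != nrow(M)) stop("`p0` length does not match `M`")
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-9) {
    stop("`p0` must be a probability vector summing to 1")
  }
  ids <- rownames(M)
  p0 <- as.numeric(p0)
  Mt <- t(M)
  g <- cfg$gamma
  p <- p0
  trace <- if (keep_trace) vector("list", cfg$max_iter)
  for (it in seq_len(cfg$max_iter)) {
    p_next <- as.numeric((1 - g) * (Mt %*% p) + g * p0)
    residual <- sum(abs(p_next - p))
    p <- p_next
    if (keep_trace) {
      trace[[it]] <- c(iteration = it, residual = residual, total_mass = sum(p))
    }
    if (residual <= cfg$tol) {
      names(p) <- ids
      out <- list(p = p, iterations = it, residual = residual)
      if (keep_trace) {
        out$trace <- as.data.frame(do.call(rbind, trace[seq_len(it)]))
      }
      return(structure(out, class = "stationary_result"))
    }
  }
  no_convergence_error(cfg$max_iter, residual)
}

#' @export
print.stationary_result <- function(x, ...) {
  cat("<stationary_result> ", length(x$p), " nodes, converged in ",
      x$iterations, " iterations (L1 residual ",
      format(x$residual, digits = 3), ")\n", sep = "")
  invisible(x)
}

# Deterministic ranking: descending score, ties by ascending identifier.
rank_candidates <- function(scores) {
  ids <- names(scores)
  ord <- order(-scores, ids)
  data.frame(rank = seq_along(ord), gene = ids[ord],
             score = as.numeric(scores[ord]), stringsAsFactors = FALSE)
}

#' Prioritize candidate genes by multigraph random walk
#'
#' Runs the restart walk on the merged multigraph, seeding at the known
#' genes, and ranks the candidates by their stationary probability
#' (descending; ties broken by ascending identifier).
#'
#' @param mg a [gene_multigraph()]
#' @param seeds non-empty set of known gene identifiers (source nodes)
#' @param candidates set of candidate gene identifiers, disjoint from
#'   `seeds`
#' @param cfg a [walk_config()]
#' @param transition optional precomputed [merge_transition()] matrix of
#'   `mg`, to amortize the merge over repeated calls
#' @return data frame with columns `rank`, `gene`, `score`
#' @export
prioritize <- function(mg, seeds, candidates, cfg = walk_config(),
                       transition = NULL) {
  stopifnot(inherits(mg, "gene_multigraph"))
  seeds <- unique(as.character(seeds))
  candidates <- unique(as.character(candidates))
  if (length(candidates) == 0L) stop("candidate set is empty")
  bad <- setdiff(candidates, mg$universe)
  if (length(bad)) stop("candidate(s) not in universe: ", paste(bad, collapse = ", "))
  if (length(intersect(seeds, candidates))) {
    stop("seeds and candidates must be disjoint: ",
         paste(intersect(seeds, candidates), collapse = ", "))
  }
  M <- if (is.null(transition)) merge_transition(mg) else transition
  p0 <- initial_distribution(mg$universe, seeds)
  res <- rwr(M, p0, cfg)
  rank_candidates(res$p[candidates])
}
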