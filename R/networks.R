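#' Weighted undirected network
#'
#' Container for a single-source weighted undirected graph: one layer of a
#' gene multigraph, or a phenotype similarity (KNN) graph. Nodes are opaque
#' string identifiers; the node set is exactly the set of endpoints of the
#' edge list, so every retained node has at least one incident edge — the
#' precondition the random-walk transition matrix needs (every row of the
#' adjacency matrix must have positive sum).
#'
#' @param edges data frame with columns `from`, `to` and optionally
#'   `weight` (default 1). Edges are undirected; each unordered pair may
#'   appear at most once. Self-loops and non-positive weights are rejected.
#' @param node_ids optional character vector fixing the node order; must be
#'   a permutation of the identifiers appearing in `edges`. Defaults to
#'   sorted order.
#' @return object of class `weighted_network` with elements `node_ids` and
#'   `edges` (canonicalized so `from < to`).
#' @examples
#' net <- weighted_network(data.frame(from = "a", to = "b", weight = 0.5))
#' adjacency_matrix(net)
#' @export
weighted_network <- function(edges, node_ids = NULL) {
  if (!is.data.frame(edges) || !all(c("from", "to") %in% names(edges))) {
    stop("`edges` must be a data frame with columns `from` and `to`")
  }
  if (nrow(edges) == 0L) stop("network has no edges")
  from <- trimws(as.character(edges$from))
  to <- trimws(as.character(edges$to))
  weight <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, length(from))
  if (anyNA(from) || anyNA(to) || any(from == "") || any(to == "")) {
    stop("edge endpoints must be non-missing, non-empty identifiers")
  }
  if (anyNA(weight) || any(!is.finite(weight)) || any(weight <= 0)) {
    stop("edge weights must be finite and strictly positive")
  }
  if (any(from == to)) {
    stop("self-loops are not allowed: ", paste(unique(from[from == to]), collapse = ", "))
  }
  # canonical orientation so duplicate detection is order-independent
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate edges: ", paste(gsub("\r", "--", dup), collapse = ", "))
  }
  present <- sort(unique(c(a, b)))
  if (is.null(node_ids)) {
    node_ids <- present
  } else {
    node_ids <- trimws(as.character(node_ids))
    if (anyDuplicated(node_ids)) stop("`node_ids` contains duplicates")
    if (!setequal(node_ids, present)) {
      extra <- setdiff(node_ids, present)
      missing <- setdiff(present, node_ids)
      if (length(extra)) {
        stop("isolated nodes are not retained; drop them at construction: ",
             paste(extra, collapse = ", "))
      }
      stop("`node_ids` is missing edge endpoints: ", paste(missing, collapse = ", "))
    }
  }
  ord <- order(a, b)
  structure(
    list(node_ids = node_ids,
         edges = data.frame(from = a[ord], to = b[ord], weight = weight[ord],
                            stringsAsFactors = FALSE)),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("<weighted_network> ", length(x$node_ids), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Symmetric adjacency matrix of a weighted network
#'
#' @param net a [weighted_network()]
#' @return dense symmetric numeric matrix in `net$node_ids` order
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  ids <- net$node_ids
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(net$edges$from, ids)
  j <- match(net$edges$to, ids)
  A[cbind(i, j)] <- net$edges$weight
  A[cbind(j, i)] <- net$edges$weight
  A
}

# Checks a similarity matrix: square, named, non-negative, symmetric within tol.
validate_similarity <- function(sim, tol = 1e-9) {
  if (!is.matrix(sim) || !is.numeric(sim)) stop("similarity must be a numeric matrix")
  if (nrow(sim) != ncol(sim)) stop("similarity matrix must be square")
  ids <- rownames(sim)
  if (is.null(ids) || is.null(colnames(sim))) {
    stop("similarity matrix must carry node identifiers as dimnames")
  }
  if (!identical(ids, colnames(sim))) stop("row and column identifiers differ")
  if (anyDuplicated(ids)) stop("duplicate node identifiers in similarity matrix")
  if (anyNA(sim)) stop("similarity matrix contains missing values")
  dev <- max(abs(sim - t(sim)))
  if (dev > tol) {
    stop(sprintf("similarity matrix is asymmetric (max deviation %.3g > %.3g)", dev, tol))
  }
  invisible(sim)
}

#' Build a K-nearest-neighbour similarity graph
#'
#' Connects every node to its `k` most similar partners; the edge set is the
#' union of the per-node selections, so a node picked by several others ends
#' up with degree above `k`. Edge weights equal the similarity score.
#' Self-similarity is ignored, partners with similarity <= 0 are never
#' selected, and ties at the k-th similarity are broken by ascending node
#' identifier so the output is deterministic.
#'
#' @param sim square symmetric numeric matrix with node identifiers as
#'   dimnames; the diagonal is ignored
#' @param k number of nearest neighbours per node; must satisfy
#'   `1 <= k < nrow(sim)`
#' @return a [weighted_network()]
#' @examples
#' s <- matrix(c(0, .5, .5, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' build_knn_graph(s, k = 1)
#' @export
build_knn_graph <- function(sim, k) {
  validate_similarity(sim)
  n <- nrow(sim)
  if (n < 2L) stop("need at least 2 nodes to build a KNN graph")
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) stop("`k` must be a positive integer")
  if (k >= n) stop(sprintf("k (%d) must be smaller than the node count (%d)", k, n))
  ids <- rownames(sim)
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sim[, i]
    s[i] <- -Inf
    keep <- which(s > 0)
    if (!length(keep)) next
    ord <- keep[order(-s[keep], ids[keep])]
    nb <- ord[seq_len(min(k, length(ord)))]
    pairs[[i]] <- data.frame(from = ids[i], to = ids[nb], weight = sim[nb, i],
                             stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) stop("no positive similarities; KNN graph would be empty")
  a <- pmin(pairs$from, pairs$to)
  b <- pmax(pairs$from, pairs$to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  weighted_network(data.frame(from = a[keep], to = b[keep],
                              weight = pairs$weight[keep],
                              stringsAsFactors = FALSE))
}

#' Row-stochastic transition matrix of a network
#'
#' Degree-normalizes the symmetric adjacency matrix: the probability of
#' stepping from node i to node j is `A[i, j] / d(i)` where `d(i)` is the
#' total edge weight incident to i. Because every retained node has at
#' least one edge, every row sums to one.
#'
#' @param net a [weighted_network()]
#' @return dense row-stochastic matrix (row = from, column = to, zero
#'   diagonal) in `net$node_ids` order
#' @export
transition_from_network <- function(net) {
  A <- adjacency_matrix(net)
  d <- rowSums(A)
  if (any(d <= 0)) {
    stop("isolated node(s) have no outgoing probability; drop them at construction: ",
         paste(rownames(A)[d <= 0], collapse = ", "))
  }
  A / d
}

# Internal: assert a matrix is row-stochastic within tol.
validate_transition <- function(M, tol = 1e-9) {
  if (any(M < -tol)) stop("transition matrix has negative entries")
  bad <- abs(rowSums(M) - 1) > tol
  if (any(bad)) {
    stop("transition matrix rows do not sum to 1: ",
         paste(rownames(M)[bad], collapse = ", "))
  }
  invisible(M)
}

#' Gene functional similarity from shared annotation terms
#'
#' Scores a gene pair by the overlap of their annotation-term sets (for
#' example Gene Ontology terms from one subontology). `count` mode returns
#' the raw intersection size; `jaccard` mode normalizes by the union size
#' (0 when both sets are empty).
#'
#' @param annotations named list mapping gene identifiers to character
#'   vectors of term identifiers (may be empty)
#' @param mode `"count"` (default) or `"jaccard"`
#' @return symmetric numeric similarity matrix over the genes, in the order
#'   given; the diagonal holds each gene's self-overlap and is ignored by
#'   graph construction
#' @export
annotation_overlap_similarity <- function(annotations, mode = c("count", "jaccard")) {
  mode <- match.arg(mode)
  if (!is.list(annotations) || is.null(names(annotations)) ||
      anyDuplicated(names(annotations))) {
    stop("`annotations` must be a named list with unique gene identifiers")
  }
  if (length(annotations) < 2L) stop("need at least 2 genes")
  genes <- names(annotations)
  sets <- lapply(annotations, function(x) unique(as.character(x)))
  terms <- sort(unique(unlist(sets, use.names = FALSE)))
  n <- length(genes)
  if (length(terms) == 0L) {
    inter <- matrix(0, n, n, dimnames = list(genes, genes))
  } else {
    X <- matrix(0, n, length(terms), dimnames = list(genes, terms))
    for (g in seq_len(n)) X[g, match(sets[[g]], terms)] <- 1
    inter <- X %*% t(X)
  }
  if (mode == "count") return(inter)
  sizes <- vapply(sets, length, integer(1))
  un <- outer(sizes, sizes, "+") - inter
  out <- ifelse(un > 0, inter / un, 0)
  dimnames(out) <- list(genes, genes)
  out
}
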