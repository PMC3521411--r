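#' Gene multigraph: an ordered collection of network layers
#'
#' Holds one [weighted_network()] per data source over a shared node
#' universe. A node may be absent from some layers; `N_i` counts the layers
#' in which node i has at least one incident edge, and every universe node
#' must appear in at least one layer (an edgeless node would have no
#' outgoing transition probability).
#'
#' @param layers list of [weighted_network()] objects (optionally named;
#'   default names `layer1`, `layer2`, ...)
#' @param universe optional character vector fixing the node order; must
#'   cover every layer node and contain nothing else. Defaults to the
#'   sorted union of layer node sets.
#' @param layer_weights optional numeric vector, one weight per layer,
#'   giving the probability of selecting each layer when leaving a node
#'   that belongs to it. For every node the weights of its member layers
#'   must sum to 1. `NULL` (default) selects uniformly among the node's
#'   member layers (weight `1/N_i`).
#' @return object of class `gene_multigraph` with elements `universe`,
#'   `layers`, `layer_weights` and `membership` (logical node x layer
#'   matrix)
#' @seealso [merge_transition()], [prioritize()]
#' @export
gene_multigraph <- function(layers, universe = NULL, layer_weights = NULL) {
  if (!is.list(layers) || length(layers) == 0L ||
      !all(vapply(layers, inherits, logical(1), "weighted_network"))) {
    stop("`layers` must be a non-empty list of weighted_network objects")
  }
  if (is.null(names(layers)) || any(names(layers) == "")) {
    names(layers) <- paste0("layer", seq_along(layers))
  }
  layer_nodes <- lapply(layers, `[[`, "node_ids")
  present <- sort(unique(unlist(layer_nodes, use.names = FALSE)))
  if (is.null(universe)) {
    universe <- present
  } else {
    universe <- trimws(as.character(universe))
    if (anyDuplicated(universe)) stop("`universe` contains duplicates")
    missing <- setdiff(present, universe)
    if (length(missing)) {
      stop("layer nodes missing from universe: ", paste(missing, collapse = ", "))
    }
    orphan <- setdiff(universe, present)
    if (length(orphan)) {
      stop("universe nodes absent from every layer (N_i = 0): ",
           paste(orphan, collapse = ", "))
    }
  }
  membership <- vapply(layer_nodes, function(nd) universe %in% nd,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, names(layers)))
  if (!is.null(layer_weights)) {
    if (!is.numeric(layer_weights) || length(layer_weights) != length(layers)) {
      stop("`layer_weights` must be numeric, one weight per layer")
    }
    if (any(layer_weights < 0)) stop("`layer_weights` must be non-negative")
    per_node <- membership %*% layer_weights
    bad <- abs(per_node - 1) > 1e-9
    if (any(bad)) {
      stop("layer weights of member layers must sum to 1 for every node; ",
           "violated at: ", paste(universe[bad], collapse = ", "))
    }
  }
  structure(
    list(universe = universe, layers = layers,
         layer_weights = layer_weights, membership = membership),
    class = "gene_multigraph"
  )
}

#' @export
print.gene_multigraph <- function(x, ...) {
  cat("<gene_multigraph> ", length(x$universe), " nodes, ",
      length(x$layers), " layers (",
      paste(names(x$layers), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Number of layers containing each node
#'
#' @param mg a [gene_multigraph()]
#' @return named integer vector `N_i` over the universe
#' @export
layer_counts <- function(mg) {
  stopifnot(inherits(mg, "gene_multigraph"))
  n <- rowSums(mg$membership)
  storage.mode(n) <- "integer"
  n
}

#' Merged transition matrix of a multigraph
#'
#' The walker at node i first selects one of the `N_i` layers containing i
#' (uniformly by default, or by the configured layer weights) and then takes
#' a degree-normalized step inside that layer. The merged transition
#' probability is therefore the expectation of the per-layer transition
#' probabilities:
#' `M[i, j] = sum_k q_i^(k) * M^(k)[i, j]` with `q_i^(k) = 1/N_i` by
#' default, summed over the layers that contain node i.
#'
#' @param mg a [gene_multigraph()]
#' @return dense row-stochastic matrix over `mg$universe`
#' @examples
#' mg <- toy_multigraph()
#' merge_transition(mg)["g1", "g2"]  # 1/2 * 1/2 + 1/2 * 1 = 0.75
#' @export
merge_transition <- function(mg) {
  stopifnot(inherits(mg, "gene_multigraph"))
  ids <- mg$universe
  n <- length(ids)
  Ni <- rowSums(mg$membership)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_along(mg$layers)) {
    layer <- mg$layers[[k]]
    Mk <- transition_from_network(layer)
    rows <- match(layer$node_ids, ids)
    cols <- rows
    q <- if (is.null(mg$layer_weights)) 1 / Ni[rows] else mg$layer_weights[k]
    M[rows, cols] <- M[rows, cols] + q * Mk
  }
  validate_transition(M)
  M
}
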