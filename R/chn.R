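#' Bipartite gene-phenotype association table
#'
#' Binary incidence matrix B (genes x phenotypes) encoding known
#' phenotype-gene relationships. Genes with at least one association and
#' phenotypes with at least one associated gene are the *bridging nodes* of
#' the heterogeneous network; all other nodes are *internal*.
#'
#' @param pairs data frame with columns `gene` and `phenotype`, one
#'   association per row; duplicates are rejected
#' @param gene_ids,phenotype_ids optional orderings; must cover every
#'   identifier in `pairs` (extra identifiers become all-zero rows/columns,
#'   i.e. internal nodes). Default: sorted identifiers of `pairs`.
#' @return object of class `association_table` with elements `gene_ids`,
#'   `phenotype_ids` and the binary matrix `B`
#' @export
association_table <- function(pairs, gene_ids = NULL, phenotype_ids = NULL) {
  if (!is.data.frame(pairs) || !all(c("gene", "phenotype") %in% names(pairs))) {
    stop("`pairs` must be a data frame with columns `gene` and `phenotype`")
  }
  g <- trimws(as.character(pairs$gene))
  p <- trimws(as.character(pairs$phenotype))
  key <- paste(g, p, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate associations: ", paste(gsub("\r", "--", dup), collapse = ", "))
  }
  if (is.null(gene_ids)) gene_ids <- sort(unique(g))
  if (is.null(phenotype_ids)) phenotype_ids <- sort(unique(p))
  gene_ids <- as.character(gene_ids)
  phenotype_ids <- as.character(phenotype_ids)
  if (anyDuplicated(gene_ids) || anyDuplicated(phenotype_ids)) {
    stop("identifier lists contain duplicates")
  }
  if (length(setdiff(g, gene_ids))) {
    stop("association gene(s) missing from `gene_ids`: ",
         paste(setdiff(g, gene_ids), collapse = ", "))
  }
  if (length(setdiff(p, phenotype_ids))) {
    stop("association phenotype(s) missing from `phenotype_ids`: ",
         paste(setdiff(p, phenotype_ids), collapse = ", "))
  }
  B <- matrix(0, length(gene_ids), length(phenotype_ids),
              dimnames = list(gene_ids, phenotype_ids))
  if (length(g)) B[cbind(match(g, gene_ids), match(p, phenotype_ids))] <- 1
  structure(list(gene_ids = gene_ids, phenotype_ids = phenotype_ids, B = B),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat("<association_table> ", length(x$gene_ids), " genes x ",
      length(x$phenotype_ids), " phenotypes, ", sum(x$B), " associations\n",
      sep = "")
  invisible(x)
}

#' @rdname association_table
#' @param at an `association_table`
#' @export
bridging_genes <- function(at) at$gene_ids[rowSums(at$B) > 0]

#' @rdname association_table
#' @export
bridging_phenotypes <- function(at) at$phenotype_ids[colSums(at$B) > 0]

#' Complex heterogeneous gene-phenotype network
#'
#' Couples a gene multigraph and a phenotype network through a bipartite
#' association table. A walker at a bridging node jumps to the other
#' subnetwork with probability `lambda` and stays in its home subnetwork
#' with probability `1 - lambda`; internal nodes walk as if the other
#' subnetwork did not exist. `eta` weights the initial restart mass given
#' to phenotype seeds versus gene seeds.
#'
#' @param genes a [gene_multigraph()]
#' @param phenotypes a [weighted_network()] over phenotype identifiers
#'   (typically a KNN graph of a phenotype similarity matrix)
#' @param associations an [association_table()]; its gene identifiers must
#'   lie in the multigraph universe and its phenotype identifiers in the
#'   phenotype network
#' @param lambda jumping probability in \[0, 1); `lambda = 0` decouples the
#'   two subnetworks
#' @param eta phenotype-side weight of the initial distribution, in (0, 1)
#' @return object of class `heterogeneous_network`
#' @export
heterogeneous_network <- function(genes, phenotypes, associations,
                                  lambda = 0.5, eta = 0.5) {
  stopifnot(inherits(genes, "gene_multigraph"),
            inherits(phenotypes, "weighted_network"),
            inherits(associations, "association_table"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda >= 1) {
    stop("`lambda` must be a single number in [0, 1)")
  }
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0 || eta >= 1) {
    stop("`eta` must be a single number in (0, 1)")
  }
  bad_g <- setdiff(associations$gene_ids, genes$universe)
  if (length(bad_g)) {
    stop("association gene(s) missing from the gene universe: ",
         paste(bad_g, collapse = ", "))
  }
  bad_p <- setdiff(associations$phenotype_ids, phenotypes$node_ids)
  if (length(bad_p)) {
    stop("association phenotype(s) missing from the phenotype network: ",
         paste(bad_p, collapse = ", "))
  }
  structure(list(genes = genes, phenotypes = phenotypes,
                 associations = associations, lambda = lambda, eta = eta),
            class = "heterogeneous_network")
}

#' @export
print.heterogeneous_network <- function(x, ...) {
  cat("<heterogeneous_network> ", length(x$genes$universe), " genes (",
      length(x$genes$layers), " layers) + ", length(x$phenotypes$node_ids),
      " phenotypes, ", sum(x$associations$B), " associations, lambda = ",
      x$lambda, ", eta = ", x$eta, "\n", sep = "")
  invisible(x)
}

# Expands the association matrix to full gene-universe x phenotype-network
# dimensions (zero rows/columns for identifiers absent from the table).
full_incidence <- function(h) {
  gids <- h$genes$universe
  pids <- h$phenotypes$node_ids
  B <- matrix(0, length(gids), length(pids), dimnames = list(gids, pids))
  at <- h$associations
  B[at$gene_ids, at$phenotype_ids] <- at$B
  B
}

#' Block transition matrix of the heterogeneous network
#'
#' Assembles the (genes + phenotypes)-square transition matrix from four
#' blocks: the merged gene-gene transitions and the phenotype-phenotype
#' transitions on the diagonal, and the association-derived cross blocks
#' off the diagonal. Rows of bridging nodes are rescaled by `1 - lambda`
#' inside their home subnetwork; the jumping mass `lambda` is spread
#' uniformly over the node's associations (row of B for genes, column of B
#' for phenotypes). Internal-node rows are left untouched, so every row
#' still sums to one.
#'
#' @param h a [heterogeneous_network()]
#' @param gene_transition optional precomputed [merge_transition()] of
#'   `h$genes` (the gene block does not depend on the associations, so it
#'   can be reused when B changes, e.g. across cross-validation trials)
#' @return dense row-stochastic matrix over `c(genes, phenotypes)`
#' @examples
#' M <- chn_transition(toy_chn())
#' M["g2", "g3"]  # 4/9 * (1 - 0.5) = 0.22
#' M["g1", "g2"]  # internal node, unchanged: 0.75
#' @export
chn_transition <- function(h, gene_transition = NULL) {
  stopifnot(inherits(h, "heterogeneous_network"))
  lambda <- h$lambda
  M_G <- if (is.null(gene_transition)) merge_transition(h$genes) else gene_transition
  M_P <- transition_from_network(h$phenotypes)
  B <- full_incidence(h)
  gids <- rownames(B)
  pids <- colnames(B)
  gene_assoc <- rowSums(B)
  phen_assoc <- colSums(B)

  M_GP <- matrix(0, length(gids), length(pids), dimnames = dimnames(B))
  bridge_g <- which(gene_assoc > 0)
  for (i in bridge_g) {
    intra <- sum(M_G[i, ])
    if (intra > 0) {
      M_G[i, ] <- M_G[i, ] * (1 - lambda)
      M_GP[i, ] <- lambda * B[i, ] / gene_assoc[i]
    } else {
      # no home-subnetwork options: all mass jumps (cannot leak probability)
      warning("gene ", gids[i], " has associations but no gene edges; ",
              "full row mass assigned to the phenotype side")
      M_GP[i, ] <- B[i, ] / gene_assoc[i]
    }
  }

  M_PG <- matrix(0, length(pids), length(gids),
                 dimnames = list(pids, gids))
  bridge_p <- which(phen_assoc > 0)
  for (j in bridge_p) {
    intra <- sum(M_P[j, ])
    if (intra > 0) {
      M_P[j, ] <- M_P[j, ] * (1 - lambda)
      M_PG[j, ] <- lambda * B[, j] / phen_assoc[j]
    } else {
      warning("phenotype ", pids[j], " has associations but no phenotype edges; ",
              "full row mass assigned to the gene side")
      M_PG[j, ] <- B[, j] / phen_assoc[j]
    }
  }

  M <- rbind(cbind(M_G, M_GP), cbind(M_PG, M_P))
  validate_transition(M)
  M
}

#' Initial distribution over the heterogeneous network
#'
#' Splits unit restart mass between the two subnetworks:
#' `p0 = c((1 - eta) * u0, eta * v0)` with `u0` uniform over the gene seeds
#' and `v0` uniform over the phenotype seeds. If one side has no seeds the
#' full mass goes to the other side (reported via a message), so the vector
#' always sums to one.
#'
#' @param h a [heterogeneous_network()]
#' @param gene_seeds gene identifiers (may be empty)
#' @param phenotype_seeds phenotype identifiers (may be empty; not both)
#' @param eta phenotype-side weight; defaults to `h$eta`
#' @return named probability vector over `c(genes, phenotypes)`
#' @export
chn_initial <- function(h, gene_seeds, phenotype_seeds, eta = h$eta) {
  stopifnot(inherits(h, "heterogeneous_network"))
  gene_seeds <- unique(as.character(gene_seeds))
  phenotype_seeds <- unique(as.character(phenotype_seeds))
  if (length(gene_seeds) == 0L && length(phenotype_seeds) == 0L) {
    stop("at least one gene or phenotype seed is required")
  }
  bad <- setdiff(gene_seeds, h$genes$universe)
  if (length(bad)) stop("gene seed(s) not in universe: ", paste(bad, collapse = ", "))
  bad <- setdiff(phenotype_seeds, h$phenotypes$node_ids)
  if (length(bad)) {
    stop("phenotype seed(s) not in phenotype network: ", paste(bad, collapse = ", "))
  }
  u0 <- stats::setNames(numeric(length(h$genes$universe)), h$genes$universe)
  v0 <- stats::setNames(numeric(length(h$phenotypes$node_ids)), h$phenotypes$node_ids)
  if (length(gene_seeds)) u0[gene_seeds] <- 1 / length(gene_seeds)
  if (length(phenotype_seeds)) v0[phenotype_seeds] <- 1 / length(phenotype_seeds)
  if (length(gene_seeds) == 0L) {
    message("no gene seeds; full initial mass placed on phenotype seeds")
    w_gene <- 0
  } else if (length(phenotype_seeds) == 0L) {
    message("no phenotype seeds; full initial mass placed on gene seeds")
    w_gene <- 1
  } else {
    w_gene <- 1 - eta
  }
  c(w_gene * u0, (1 - w_gene) * v0)
}

#' Rank genes and phenotypes on the heterogeneous network
#'
#' Runs the restart walk on the block transition matrix and splits the
#' stationary vector into its gene part `u` and phenotype part `v`.
#' Candidate genes are ranked by `u` and phenotypes by `v`, descending,
#' ties broken by ascending identifier.
#'
#' @inheritParams chn_initial
#' @param candidates candidate gene identifiers to rank (disjoint from
#'   `gene_seeds`)
#' @param cfg a [walk_config()]
#' @param transition optional precomputed [chn_transition()] matrix
#' @return list with data frames `genes` (columns `rank`, `gene`, `score`)
#'   and `phenotypes` (columns `rank`, `phenotype`, `score`), plus the
#'   `stationary_result`
#' @export
chn_rank <- function(h, gene_seeds, phenotype_seeds, candidates,
                     cfg = walk_config(), transition = NULL) {
  stopifnot(inherits(h, "heterogeneous_network"))
  candidates <- unique(as.character(candidates))
  if (length(candidates) == 0L) stop("candidate set is empty")
  bad <- setdiff(candidates, h$genes$universe)
  if (length(bad)) stop("candidate(s) not in universe: ", paste(bad, collapse = ", "))
  overlap <- intersect(candidates, as.character(gene_seeds))
  if (length(overlap)) {
    stop("gene seeds and candidates must be disjoint: ",
         paste(overlap, collapse = ", "))
  }
  M <- if (is.null(transition)) chn_transition(h) else transition
  p0 <- chn_initial(h, gene_seeds, phenotype_seeds)
  res <- rwr(M, p0, cfg)
  n_gene <- length(h$genes$universe)
  u <- res$p[seq_len(n_gene)]
  v <- res$p[-seq_len(n_gene)]
  phen <- rank_candidates(v)
  names(phen)[names(phen) == "gene"] <- "phenotype"
  list(genes = rank_candidates(u[candidates]), phenotypes = phen,
       stationary = res)
}
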