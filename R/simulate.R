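#' Specification of a synthetic multilayer benchmark
#'
#' Describes a planted-module benchmark emulating the structure network
#' propagation exploits: groups of functionally related genes that are
#' densely interconnected in several data-source layers, phenotypes whose
#' similarity mirrors the gene modules, and sparse gene-phenotype
#' associations tying the two sides together. With the defaults
#' (within-module edge probability 0.9 versus background 0.01, phenotype
#' similarity 0.8 versus 0.1) the planted signal is strong — the "easy
#' regime"; setting the within- and background-parameters equal removes
#' the signal entirely and yields a null benchmark.
#'
#' @param n_genes total genes (default 400)
#' @param n_layers gene network layers (default 3)
#' @param n_phenotypes phenotypes, assigned to modules round-robin
#'   (default 40)
#' @param n_modules planted gene modules (default 20)
#' @param module_size genes per module (default 10); the first
#'   `n_modules * module_size` genes are module members, the rest are
#'   background
#' @param within_module_edge_prob per-layer edge probability inside a
#'   module (default 0.9)
#' @param background_edge_prob per-layer edge probability elsewhere
#'   (default 0.01)
#' @param phenotype_within_similarity similarity of phenotypes sharing a
#'   module, before noise (default 0.8)
#' @param phenotype_background_similarity similarity of unrelated
#'   phenotypes, before noise (default 0.1)
#' @param similarity_noise half-width of the uniform noise added to every
#'   phenotype similarity (default 0.05)
#' @param pgr_per_module associated genes drawn per phenotype from its
#'   module (default 3)
#' @param n_chromosomes synthetic chromosomes; genes are shuffled across
#'   them so linkage intervals mix module and background genes (default 3)
#' @param rng_seed integer seed from which every random stream is derived
#' @return validated list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_genes = 400L, n_layers = 3L, n_phenotypes = 40L,
                           n_modules = 20L, module_size = 10L,
                           within_module_edge_prob = 0.9,
                           background_edge_prob = 0.01,
                           phenotype_within_similarity = 0.8,
                           phenotype_background_similarity = 0.1,
                           similarity_noise = 0.05,
                           pgr_per_module = 3L, n_chromosomes = 3L,
                           rng_seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_layers = as.integer(n_layers),
               n_phenotypes = as.integer(n_phenotypes),
               n_modules = as.integer(n_modules),
               module_size = as.integer(module_size),
               within_module_edge_prob = within_module_edge_prob,
               background_edge_prob = background_edge_prob,
               phenotype_within_similarity = phenotype_within_similarity,
               phenotype_background_similarity = phenotype_background_similarity,
               similarity_noise = similarity_noise,
               pgr_per_module = as.integer(pgr_per_module),
               n_chromosomes = as.integer(n_chromosomes),
               rng_seed = as.integer(rng_seed))
  counts <- spec[c("n_genes", "n_layers", "n_phenotypes", "n_modules",
                   "module_size", "pgr_per_module", "n_chromosomes")]
  if (any(vapply(counts, function(x) is.na(x) || x < 1L, logical(1)))) {
    stop("all counts must be positive integers")
  }
  probs <- unlist(spec[c("within_module_edge_prob", "background_edge_prob",
                         "phenotype_within_similarity",
                         "phenotype_background_similarity")])
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must lie in [0, 1]")
  if (spec$similarity_noise < 0) stop("`similarity_noise` must be >= 0")
  if (spec$n_modules * spec$module_size > spec$n_genes) {
    stop("module_size * n_modules exceeds n_genes")
  }
  if (spec$pgr_per_module > spec$module_size) {
    stop("pgr_per_module cannot exceed module_size")
  }
  structure(spec, class = "synthetic_spec")
}

# One RNG stream per generated object, each derived from the master seed,
# so regenerating one artifact never perturbs the draws of another.
substream <- function(seed, index) {
  set.seed((as.integer(seed) %% 1000003L) * 2011L + index)
}

random_layer <- function(spec, module_of, k) {
  substream(spec$rng_seed, k)
  n <- spec$n_genes
  genes <- names(module_of)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  same <- module_of[i] > 0 & module_of[i] == module_of[j]
  p <- ifelse(same, spec$within_module_edge_prob, spec$background_edge_prob)
  keep <- stats::runif(length(p)) < p
  if (!any(keep)) stop("layer has no edges; raise the edge probabilities")
  data.frame(from = genes[i[keep]], to = genes[j[keep]], weight = 1,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic planted-module benchmark
#'
#' Produces every input the evaluation protocol needs, reproducibly from
#' `spec$rng_seed`: a gene multigraph with shared planted modules across
#' independent layers, a block-structured phenotype similarity matrix
#' aligned to the modules, a bipartite association table linking each
#' phenotype to genes of its module, disease gene sets (one disease per
#' module), and gene positions laid out uniformly along shuffled synthetic
#' chromosomes so linkage intervals mix module and background genes.
#' Genes left without any edge in every layer are attached to their gene
#' neighbour by index in layer 1, keeping the multigraph invariant
#' (every node in at least one layer) intact.
#'
#' @param spec a [synthetic_spec()]
#' @return list of class `multiwalk_benchmark` with elements `multigraph`,
#'   `phenotype_similarity`, `associations`, `disease_sets`, `positions`
#'   and `spec`
#' @export
generate_benchmark <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  width <- max(4L, nchar(as.character(spec$n_genes)))
  genes <- sprintf(paste0("gene%0", width, "d"), seq_len(spec$n_genes))
  module_of <- rep(0L, spec$n_genes)
  module_of[seq_len(spec$n_modules * spec$module_size)] <-
    rep(seq_len(spec$n_modules), each = spec$module_size)
  names(module_of) <- genes

  layer_edges <- lapply(seq_len(spec$n_layers), function(k)
    random_layer(spec, module_of, k))

  # repair genes isolated in every layer so the universe is walkable
  covered <- unique(unlist(lapply(layer_edges, function(e) c(e$from, e$to))))
  lonely <- setdiff(genes, covered)
  if (length(lonely)) {
    partner <- genes[match(lonely, genes) %% spec$n_genes + 1L]
    layer_edges[[1L]] <- rbind(layer_edges[[1L]],
                               data.frame(from = lonely, to = partner,
                                          weight = 1, stringsAsFactors = FALSE))
  }
  layers <- lapply(layer_edges, weighted_network)
  names(layers) <- paste0("layer", seq_len(spec$n_layers))
  mg <- gene_multigraph(layers, universe = genes)

  phen <- sprintf("Ph%03d", seq_len(spec$n_phenotypes))
  phen_module <- rep_len(seq_len(spec$n_modules), spec$n_phenotypes)
  substream(spec$rng_seed, 101L)
  np <- spec$n_phenotypes
  sim <- matrix(0, np, np, dimnames = list(phen, phen))
  base <- ifelse(outer(phen_module, phen_module, "=="),
                 spec$phenotype_within_similarity,
                 spec$phenotype_background_similarity)
  noise <- matrix(stats::runif(np * np, -spec$similarity_noise,
                               spec$similarity_noise), np, np)
  upper <- upper.tri(sim)
  sim[upper] <- pmin(1, pmax(0, base[upper] + noise[upper]))
  sim <- sim + t(sim)
  diag(sim) <- 1

  substream(spec$rng_seed, 102L)
  pgr <- do.call(rbind, lapply(seq_len(np), function(j) {
    pool <- genes[module_of == phen_module[j]]
    data.frame(gene = sample(pool, spec$pgr_per_module),
               phenotype = phen[j], stringsAsFactors = FALSE)
  }))
  associations <- association_table(pgr, gene_ids = sort(unique(pgr$gene)),
                                    phenotype_ids = phen)

  disease_sets <- lapply(seq_len(spec$n_modules), function(m)
    genes[module_of == m])
  names(disease_sets) <- sprintf("disease%02d", seq_len(spec$n_modules))

  substream(spec$rng_seed, 103L)
  shuffled <- sample(genes)
  chrom <- rep_len(paste0("chr", seq_len(spec$n_chromosomes)), spec$n_genes)
  idx <- stats::ave(seq_along(shuffled), chrom, FUN = seq_along)
  positions <- gene_positions(data.frame(
    gene = shuffled, chrom = chrom,
    start = idx * 10000, end = idx * 10000 + 5000,
    stringsAsFactors = FALSE))
  positions <- positions[order(positions$gene), ]
  rownames(positions) <- NULL

  structure(list(multigraph = mg, phenotype_similarity = sim,
                 associations = associations, disease_sets = disease_sets,
                 positions = positions, spec = spec),
            class = "multiwalk_benchmark")
}

#' @export
print.multiwalk_benchmark <- function(x, ...) {
  cat("<multiwalk_benchmark> ", x$spec$n_genes, " genes / ",
      x$spec$n_layers, " layers / ", x$spec$n_phenotypes, " phenotypes / ",
      x$spec$n_modules, " planted modules (seed ", x$spec$rng_seed, ")\n",
      sep = "")
  invisible(x)
}
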