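#' Validate a gene position table
#'
#' @param positions data frame with columns `gene`, `chrom`, `start`,
#'   `end` (1-based inclusive base-pair coordinates, `start < end`), one
#'   row per gene
#' @return the validated data frame (invisibly usable), with a `midpoint`
#'   column added
#' @export
gene_positions <- function(positions) {
  if (!is.data.frame(positions) ||
      !all(c("gene", "chrom", "start", "end") %in% names(positions))) {
    stop("`positions` needs columns gene, chrom, start, end")
  }
  positions$gene <- trimws(as.character(positions$gene))
  positions$chrom <- trimws(as.character(positions$chrom))
  positions$start <- as.numeric(positions$start)
  positions$end <- as.numeric(positions$end)
  if (anyDuplicated(positions$gene)) {
    stop("duplicate gene(s) in position table: ",
         paste(unique(positions$gene[duplicated(positions$gene)]), collapse = ", "))
  }
  if (anyNA(positions$start) || anyNA(positions$end) ||
      any(positions$start >= positions$end)) {
    stop("every gene must satisfy start < end")
  }
  positions$midpoint <- (positions$start + positions$end) / 2
  positions
}

#' Artificial linkage interval around a held-out gene
#'
#' Returns the held-out gene plus its `n` nearest same-chromosome
#' neighbours by midpoint distance — the candidate set a linkage study
#' would put on the table. Distance ties are broken by ascending gene
#' identifier. If the chromosome holds fewer than `n` other genes, all of
#' them are taken and a warning is raised.
#'
#' @param held_out gene identifier present in `positions`
#' @param positions a [gene_positions()] table
#' @param n number of neighbours (default 99, giving a 100-gene candidate
#'   list)
#' @return character vector of candidate gene identifiers (held-out gene
#'   included), sorted
#' @export
linkage_interval <- function(held_out, positions, n = 99L) {
  positions <- gene_positions(positions)
  row <- positions[positions$gene == held_out, ]
  if (nrow(row) == 0L) stop("held-out gene not in position table: ", held_out)
  same <- positions[positions$chrom == row$chrom & positions$gene != held_out, ]
  if (nrow(same) < n) {
    warning(sprintf("chromosome %s has only %d other genes (< %d); taking all",
                    row$chrom, nrow(same), n))
  }
  d <- abs(same$midpoint - row$midpoint)
  ord <- order(d, same$gene)
  nb <- same$gene[ord][seq_len(min(n, nrow(same)))]
  sort(c(held_out, nb))
}

new_loocv_result <- function(trials, protocol) {
  structure(list(trials = trials, protocol = protocol,
                 success_count = sum(trials$success)),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("<loocv_result> ", nrow(x$trials), " trials (", x$protocol, "), ",
      x$success_count, " ranked first\n", sep = "")
  invisible(x)
}

# Consolidate per-trial notes into at most one warning per run.
warn_once <- function(msgs) {
  if (length(msgs)) warning(paste(unique(msgs), collapse = "; "), call. = FALSE)
}

#' Leave-one-out cross-validation of multigraph prioritization
#'
#' For every disease and every one of its genes: hold the gene out, seed
#' the walk at the remaining genes, rank the held-out gene's linkage
#' interval with [prioritize()] and record the held-out gene's rank. The
#' protocol is fully deterministic — there is no randomness anywhere.
#' Genes absent from the multigraph universe are dropped (warning);
#' diseases left with fewer than two genes are skipped (warning). Seeds
#' falling inside a candidate interval are removed from the candidates so
#' the two sets stay disjoint.
#'
#' @param disease_sets named list mapping disease identifiers to character
#'   vectors of gene identifiers
#' @param mg a [gene_multigraph()]
#' @param positions a [gene_positions()] table
#' @param cfg a [walk_config()]
#' @param interval_size neighbours per linkage interval (default 99)
#' @return object of class `loocv_result`: `trials` data frame (columns
#'   `disease`, `gene`, `n_candidates`, `rank`, `success`) and the total
#'   `success_count` (trials where the held-out gene scored strictly above
#'   every other candidate)
#' @export
loocv_rwrm <- function(disease_sets, mg, positions, cfg = walk_config(),
                       interval_size = 99L) {
  stopifnot(inherits(mg, "gene_multigraph"), is.list(disease_sets))
  if (is.null(names(disease_sets)) || any(names(disease_sets) == "")) {
    stop("`disease_sets` must be a named list")
  }
  positions <- gene_positions(positions)
  M <- merge_transition(mg)
  notes <- character()
  trials <- list()
  for (disease in names(disease_sets)) {
    genes <- unique(as.character(disease_sets[[disease]]))
    unknown <- setdiff(genes, mg$universe)
    if (length(unknown)) {
      notes <- c(notes, sprintf("%s: %d gene(s) not in universe dropped",
                                disease, length(unknown)))
      genes <- setdiff(genes, unknown)
    }
    if (length(genes) < 2L) {
      notes <- c(notes, sprintf("%s: fewer than 2 usable genes, skipped", disease))
      next
    }
    for (g in genes) {
      seeds <- setdiff(genes, g)
      cands <- withCallingHandlers(
        linkage_interval(g, positions, interval_size),
        warning = function(w) {
          notes <<- c(notes, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      off <- setdiff(cands, mg$universe)
      if (length(off)) {
        notes <- c(notes, "candidate gene(s) outside the universe dropped")
        cands <- setdiff(cands, off)
      }
      hit <- intersect(cands, seeds)
      if (length(hit)) {
        notes <- c(notes, "seed gene(s) inside a candidate interval removed from candidates")
        cands <- setdiff(cands, hit)
      }
      ranking <- prioritize(mg, seeds, cands, cfg, transition = M)
      r <- ranking$rank[ranking$gene == g]
      top <- ranking$score[ranking$gene == g] >
        max(c(-Inf, ranking$score[ranking$gene != g]))
      trials[[length(trials) + 1L]] <- data.frame(
        disease = disease, gene = g, n_candidates = nrow(ranking),
        rank = r, success = top, stringsAsFactors = FALSE)
    }
  }
  warn_once(notes)
  if (!length(trials)) stop("no usable LOOCV trials")
  new_loocv_result(do.call(rbind, trials), protocol = "rwrm")
}

#' Rank-based ROC/AUC of a cross-validation run
#'
#' Each trial contributes one positive (the held-out gene, at rank r among
#' n candidates) and n - 1 negatives; its AUC contribution is
#' `(n - r) / (n - 1)`, the fraction of negatives the positive outranks.
#' The overall AUC is the mean over all pooled trials and equals the
#' Mann-Whitney probability that a held-out gene outranks a random
#' candidate when all trials share a candidate-list size. Per-disease AUCs
#' average each disease's own trials. Single-candidate trials carry no
#' ranking information and are excluded with a warning.
#'
#' @param result a `loocv_result`
#' @return list with `overall_auc`, `disease_auc` (named vector),
#'   `n_trials` and `roc` (data frame of pooled ROC points: `fpr`, `tpr`
#'   over rank thresholds)
#' @export
rank_auc <- function(result) {
  stopifnot(inherits(result, "loocv_result"))
  tr <- result$trials
  drop <- tr$n_candidates < 2L
  if (any(drop)) {
    warning(sum(drop), " single-candidate trial(s) excluded from AUC")
    tr <- tr[!drop, , drop = FALSE]
  }
  if (nrow(tr) == 0L) stop("no trials with >= 2 candidates")
  contrib <- (tr$n_candidates - tr$rank) / (tr$n_candidates - 1)
  thresholds <- 0:max(tr$n_candidates)
  tpr <- vapply(thresholds, function(t) mean(tr$rank <= t), numeric(1))
  fpr <- vapply(thresholds, function(t) {
    sum(pmin(t, tr$n_candidates) - (tr$rank <= t)) / sum(tr$n_candidates - 1)
  }, numeric(1))
  list(overall_auc = mean(contrib),
       disease_auc = tapply(contrib, tr$disease, mean),
       n_trials = nrow(tr),
       roc = data.frame(fpr = fpr, tpr = tpr))
}

#' Leave-one-out cross-validation on the heterogeneous network
#'
#' For every known phenotype-gene relationship: remove it from the
#' association table, seed the walk at the target phenotype and the
#' phenotype's remaining genes, rank the held-out gene's linkage interval
#' with [chn_rank()], and count the trial a *successful prediction* when
#' the held-out gene's score is strictly greater than every other
#' candidate's. The merged gene block of the transition matrix does not
#' depend on the associations and is computed once.
#'
#' @param h a [heterogeneous_network()]
#' @param positions a [gene_positions()] table
#' @param cfg a [walk_config()]
#' @param interval_size neighbours per linkage interval (default 99)
#' @return a `loocv_result` whose `trials` carry the target phenotype in
#'   the `disease` column; `success_count` totals the strict rank-1 trials
#' @export
loocv_chn <- function(h, positions, cfg = walk_config(), interval_size = 99L) {
  stopifnot(inherits(h, "heterogeneous_network"))
  positions <- gene_positions(positions)
  M_G <- merge_transition(h$genes)
  at <- h$associations
  pairs <- which(at$B == 1, arr.ind = TRUE)
  if (nrow(pairs) == 0L) stop("association table is empty; nothing to cross-validate")
  notes <- character()
  trials <- list()
  for (idx in seq_len(nrow(pairs))) {
    g <- at$gene_ids[pairs[idx, 1]]
    ph <- at$phenotype_ids[pairs[idx, 2]]
    if (!g %in% h$genes$universe) {
      notes <- c(notes, sprintf("held-out gene %s not in universe, trial skipped", g))
      next
    }
    B2 <- at$B
    B2[g, ph] <- 0
    at2 <- association_table(
      data.frame(gene = at$gene_ids[row(B2)[B2 == 1]],
                 phenotype = at$phenotype_ids[col(B2)[B2 == 1]],
                 stringsAsFactors = FALSE),
      gene_ids = at$gene_ids, phenotype_ids = at$phenotype_ids)
    h2 <- heterogeneous_network(h$genes, h$phenotypes, at2,
                                lambda = h$lambda, eta = h$eta)
    gene_seeds <- setdiff(at$gene_ids[at$B[, ph] == 1], g)
    cands <- withCallingHandlers(
      linkage_interval(g, positions, interval_size),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    off <- setdiff(cands, h$genes$universe)
    if (length(off)) {
      notes <- c(notes, "candidate gene(s) outside the universe dropped")
      cands <- setdiff(cands, off)
    }
    hit <- intersect(cands, gene_seeds)
    if (length(hit)) {
      notes <- c(notes, "seed gene(s) inside a candidate interval removed from candidates")
      cands <- setdiff(cands, hit)
    }
    ranking <- suppressMessages(
      chn_rank(h2, gene_seeds, ph, cands, cfg,
               transition = chn_transition(h2, gene_transition = M_G))
    )$genes
    r <- ranking$rank[ranking$gene == g]
    top <- ranking$score[ranking$gene == g] >
      max(c(-Inf, ranking$score[ranking$gene != g]))
    trials[[length(trials) + 1L]] <- data.frame(
      disease = ph, gene = g, n_candidates = nrow(ranking),
      rank = r, success = top, stringsAsFactors = FALSE)
  }
  warn_once(notes)
  if (!length(trials)) stop("no usable LOOCV trials")
  new_loocv_result(do.call(rbind, trials), protocol = "chn")
}

#' Sweep the phenotype KNN-graph size K
#'
#' Rebuilds the phenotype network from the similarity matrix for each
#' requested K, reassembles the heterogeneous network and reruns
#' [loocv_chn()], tabulating the number of successful (rank-1)
#' predictions per K.
#'
#' @param k_values integer vector of KNN sizes
#' @param phenotype_similarity square symmetric phenotype similarity
#'   matrix with identifiers as dimnames
#' @param mg a [gene_multigraph()]
#' @param associations an [association_table()]
#' @param positions a [gene_positions()] table
#' @param cfg a [walk_config()]
#' @param lambda,eta heterogeneous-network parameters
#' @param interval_size neighbours per linkage interval
#' @return data frame with columns `k`, `n_trials`, `success_count`,
#'   `overall_auc`
#' @export
k_sweep <- function(k_values, phenotype_similarity, mg, associations,
                    positions, cfg = walk_config(), lambda = 0.5, eta = 0.5,
                    interval_size = 99L) {
  k_values <- as.integer(k_values)
  if (length(k_values) == 0L || anyNA(k_values)) {
    stop("`k_values` must be a non-empty integer vector")
  }
  rows <- lapply(k_values, function(k) {
    res <- tryCatch({
      phen <- build_knn_graph(phenotype_similarity, k)
      h <- heterogeneous_network(mg, phen, associations,
                                 lambda = lambda, eta = eta)
      loocv_chn(h, positions, cfg, interval_size)
    }, error = function(e) {
      stop(sprintf("K = %d: %s", k, conditionMessage(e)), call. = FALSE)
    })
    auc <- suppressWarnings(rank_auc(res)$overall_auc)
    data.frame(k = k, n_trials = nrow(res$trials),
               success_count = res$success_count, overall_auc = auc)
  })
  do.call(rbind, rows)
}
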