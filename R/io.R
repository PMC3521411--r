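#' @name multiwalk-io
#' @title TSV readers for the network, similarity and annotation dialects
#'
#' @description
#' All tables are tab-separated with no quoting. Readers validate rather
#' than repair: malformed lines, duplicate pairs and asymmetric similarity
#' matrices are errors that name the offending file and line. Identifiers
#' are whitespace-trimmed and case-preserved.
#'
#' Dialects:
#' \itemize{
#'   \item edge list: `node_a<TAB>node_b<TAB>weight`, weight optional
#'     (default 1), undirected;
#'   \item similarity matrix: first row and first column hold the node
#'     identifiers, cell (i, j) the score;
#'   \item associations: `gene<TAB>phenotype`;
#'   \item positions: `gene<TAB>chrom<TAB>start<TAB>end` (1-based inclusive,
#'     or BED-style half-open with `zero_based = TRUE`);
#'   \item disease sets: `disease<TAB>gene`;
#'   \item annotations: `gene<TAB>term`.
#' }
#' @param path file path
#' @param zero_based interpret `start` as 0-based half-open (BED dialect)
NULL

split_tsv <- function(path, n_fields, optional_last = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(path, ": file is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) == n_fields |
    (optional_last & lengths(parts) == n_fields - 1L)
  if (!all(ok)) {
    stop(sprintf("%s:%d: expected %d tab-separated fields",
                 path, which(!ok)[1], n_fields))
  }
  list(parts = parts, lines = which(nzchar(trimws(readLines(path)))))
}

pair_reader <- function(path, what) {
  tsv <- split_tsv(path, 2L)
  a <- trimws(vapply(tsv$parts, `[`, character(1), 1L))
  b <- trimws(vapply(tsv$parts, `[`, character(1), 2L))
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(key == key[which(duplicated(key))[1]])
    stop(sprintf("%s: duplicate %s pair at lines %s", path, what,
                 paste(tsv$lines[d], collapse = " and ")))
  }
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

#' @rdname multiwalk-io
#' @return `read_edge_list()`: a [weighted_network()]
#' @export
read_edge_list <- function(path) {
  tsv <- split_tsv(path, 3L, optional_last = TRUE)
  from <- trimws(vapply(tsv$parts, `[`, character(1), 1L))
  to <- trimws(vapply(tsv$parts, `[`, character(1), 2L))
  w <- vapply(tsv$parts, function(p) {
    if (length(p) < 3L) return(1)
    suppressWarnings(as.numeric(p[3]))
  }, numeric(1))
  if (anyNA(w)) {
    stop(sprintf("%s:%d: weight is not a number", path, tsv$lines[which(is.na(w))[1]]))
  }
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(key == key[which(duplicated(key))[1]])
    stop(sprintf("%s: duplicate edge at lines %s", path,
                 paste(tsv$lines[d], collapse = " and ")))
  }
  tryCatch(
    weighted_network(data.frame(from = from, to = to, weight = w,
                                stringsAsFactors = FALSE)),
    error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE))
}

#' @rdname multiwalk-io
#' @param tol maximum tolerated asymmetry before a similarity file is
#'   rejected
#' @return `read_similarity()`: a named symmetric numeric matrix
#' @export
read_similarity <- function(path, tol = 1e-6) {
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1L,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop(path, ": non-numeric similarity values")
  rownames(m) <- trimws(rownames(m))
  colnames(m) <- trimws(colnames(m))
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop(path, ": similarity matrix must be square with matching row and column identifiers")
  }
  dev <- max(abs(m - t(m)))
  if (dev > tol) {
    stop(sprintf("%s: similarity matrix asymmetric (max deviation %.3g > %.3g)",
                 path, dev, tol))
  }
  m <- (m + t(m)) / 2  # remove rounding drift from text serialization
  validate_similarity(m)
  m
}

#' @rdname multiwalk-io
#' @return `read_associations()`: an [association_table()]
#' @export
read_associations <- function(path) {
  p <- pair_reader(path, "association")
  association_table(data.frame(gene = p$a, phenotype = p$b,
                               stringsAsFactors = FALSE))
}

#' @rdname multiwalk-io
#' @return `read_positions()`: a [gene_positions()] table
#' @export
read_positions <- function(path, zero_based = FALSE) {
  tsv <- split_tsv(path, 4L)
  gene <- trimws(vapply(tsv$parts, `[`, character(1), 1L))
  chrom <- trimws(vapply(tsv$parts, `[`, character(1), 2L))
  start <- suppressWarnings(as.numeric(vapply(tsv$parts, `[`, character(1), 3L)))
  end <- suppressWarnings(as.numeric(vapply(tsv$parts, `[`, character(1), 4L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("%s:%d: non-numeric coordinate", path,
                 tsv$lines[which(is.na(start) | is.na(end))[1]]))
  }
  if (zero_based) start <- start + 1
  tryCatch(
    gene_positions(data.frame(gene = gene, chrom = chrom, start = start,
                              end = end, stringsAsFactors = FALSE)),
    error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE))
}

#' @rdname multiwalk-io
#' @return `read_disease_sets()`: named list of gene identifier vectors
#' @export
read_disease_sets <- function(path) {
  p <- pair_reader(path, "disease-gene")
  split(p$b, p$a)
}

#' @rdname multiwalk-io
#' @return `read_annotations()`: named list of term identifier vectors
#' @export
read_annotations <- function(path) {
  p <- pair_reader(path, "gene-term")
  split(p$b, p$a)
}

#' Deterministic writers for rankings, trials, networks and summaries
#'
#' Writers emit tab-separated text with a fixed column order and a fixed
#' row order, so identical inputs always produce byte-identical files.
#' Scores are printed with six decimal places.
#'
#' @param ranking data frame with columns `rank`, `gene` (or `phenotype`),
#'   `score`
#' @param path output file path
#' @name multiwalk-writers
#' @export
write_rankings <- function(ranking, path) {
  out <- ranking
  out$score <- sprintf("%.6f", out$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname multiwalk-writers
#' @param result a `loocv_result`
#' @export
write_trials <- function(result, path) {
  stopifnot(inherits(result, "loocv_result"))
  tr <- result$trials[order(result$trials$disease, result$trials$gene), ]
  utils::write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname multiwalk-writers
#' @param summary named list of results to serialize
#' @param config optional named list of run parameters recorded alongside
#' @export
write_summary <- function(summary, path, config = NULL) {
  payload <- list(results = summary, config = config,
                  versions = list(
                    multiwalk = as.character(utils::packageVersion("multiwalk")),
                    R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname multiwalk-writers
#' @param net a [weighted_network()]
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  e <- net$edges
  lines <- sprintf("%s\t%s\t%s", e$from, e$to, format(e$weight, digits = 15))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname multiwalk-writers
#' @param sim named symmetric similarity matrix
#' @export
write_similarity <- function(sim, path) {
  validate_similarity(sim)
  utils::write.table(sim, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Write a generated benchmark to a directory
#'
#' Serializes every artifact of [generate_benchmark()] in the package's
#' TSV dialects: one edge list per layer (`layer<k>.tsv`),
#' `phenotype_similarity.tsv`, `associations.tsv`, `disease_sets.tsv` and
#' `positions.tsv`.
#'
#' @param bench a `multiwalk_benchmark`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "multiwalk_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(bench$multigraph$layers)) {
    write_edge_list(bench$multigraph$layers[[k]],
                    file.path(dir, sprintf("layer%d.tsv", k)))
  }
  write_similarity(bench$phenotype_similarity,
                   file.path(dir, "phenotype_similarity.tsv"))
  at <- bench$associations
  idx <- which(at$B == 1, arr.ind = TRUE)
  idx <- idx[order(at$gene_ids[idx[, 1]], at$phenotype_ids[idx[, 2]]), , drop = FALSE]
  writeLines(sprintf("%s\t%s", at$gene_ids[idx[, 1]], at$phenotype_ids[idx[, 2]]),
             file.path(dir, "associations.tsv"))
  ds <- bench$disease_sets
  writeLines(unlist(lapply(names(ds), function(d)
    sprintf("%s\t%s", d, sort(ds[[d]])))),
    file.path(dir, "disease_sets.tsv"))
  pos <- bench$positions
  writeLines(sprintf("%s\t%s\t%d\t%d", pos$gene, pos$chrom,
                     as.integer(pos$start), as.integer(pos$end)),
             file.path(dir, "positions.tsv"))
  invisible(dir)
}
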