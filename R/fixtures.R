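#' Worked-example multigraph over four genes
#'
#' Three unit-weight layers over genes g1..g4:
#' layer 1 \{g1-g2, g1-g3, g2-g3\}, layer 2 \{g1-g2, g2-g3, g2-g4\},
#' layer 3 \{g2-g3, g2-g4\}. g1 belongs to two layers and g2 and g3 to all
#' three, so the merged transition probabilities work out to round numbers:
#' p(g1 -> g2) = 1/2 * 1/2 + 1/2 * 1 = 0.75 and
#' p(g2 -> g3) = 1/3 * (1/2 + 1/3 + 1/2) = 4/9.
#'
#' @return a [gene_multigraph()]
#' @export
toy_multigraph <- function() {
  edges <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(from = m[, 1], to = m[, 2], weight = 1, stringsAsFactors = FALSE)
  }
  gene_multigraph(list(
    layer1 = weighted_network(edges("g1", "g2", "g1", "g3", "g2", "g3")),
    layer2 = weighted_network(edges("g1", "g2", "g2", "g3", "g2", "g4")),
    layer3 = weighted_network(edges("g2", "g3", "g2", "g4"))
  ))
}

#' Rounded merged transition matrix of the five-gene worked example
#'
#' The 5x5 row-stochastic matrix used to illustrate ranking by restart
#' walk: entries are printed to two decimals (so row g3 carries 0.26 where
#' exact fractions give 0.25, making each row total exactly 1.00), and a
#' fifth gene g5 appears whose underlying layer edges are not part of
#' [toy_multigraph()]. Seeding the walk at g4 with restart 0.7 yields a
#' stationary vector whose g4 and g3 entries round to 0.71 and 0.13, with
#' g3 first among the non-seeds.
#'
#' @return dense named 5x5 matrix
#' @export
toy_merged_matrix <- function() {
  ids <- paste0("g", 1:5)
  matrix(c(
    0.00, 0.75, 0.25, 0.00, 0.00,
    0.28, 0.00, 0.44, 0.28, 0.00,
    0.08, 0.58, 0.00, 0.08, 0.26,
    0.00, 0.00, 0.50, 0.00, 0.50,
    0.00, 0.33, 0.50, 0.17, 0.00
  ), 5, 5, byrow = TRUE, dimnames = list(ids, ids))
}

#' Worked-example heterogeneous network
#'
#' Couples [toy_multigraph()] to a four-phenotype unit-weight network
#' (edges Ph1-Ph2, Ph2-Ph3, Ph2-Ph4, Ph3-Ph4) through the associations
#' g2-Ph2, g2-Ph3 and g3-Ph3, with the default jumping probability
#' `lambda = 0.5` and seed split `eta = 0.5`. The bridging nodes are
#' exactly g2, g3, Ph2 and Ph3; for example the bridging transition
#' g2 -> g3 becomes 4/9 * (1 - lambda) = 0.22 while the internal
#' transition g1 -> g2 keeps its merged value 0.75.
#'
#' @param lambda,eta passed to [heterogeneous_network()]
#' @return a [heterogeneous_network()]
#' @export
toy_chn <- function(lambda = 0.5, eta = 0.5) {
  phen <- weighted_network(data.frame(
    from = c("Ph1", "Ph2", "Ph2", "Ph3"),
    to = c("Ph2", "Ph3", "Ph4", "Ph4"),
    weight = 1, stringsAsFactors = FALSE
  ))
  assoc <- association_table(data.frame(
    gene = c("g2", "g2", "g3"),
    phenotype = c("Ph2", "Ph3", "Ph3"),
    stringsAsFactors = FALSE
  ))
  heterogeneous_network(toy_multigraph(), phen, assoc,
                        lambda = lambda, eta = eta)
}
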