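# Louvain community detection on the undirected weighted projection of the
# regulatory network, with Newman-Girvan modularity and per-community
# hypergeometric term enrichment (BH-corrected).

grn_undirected <- function(network) {
  e <- network$edges
  w <- if ("weight" %in% names(e)) e$weight else rep(1, nrow(e))
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$tf_id, to = e$tg_id, weight = w,
               stringsAsFactors = FALSE),
    directed = TRUE, vertices = network$nodes$gene_id)
  # symmetrize; parallel arcs (a->b plus b->a) sum their weights
  igraph::as_undirected(g, mode = "collapse",
                        edge.attr.comb = list(weight = "sum"))
}

#' Louvain community detection
#'
#' Blondel's two-phase greedy modularity maximization (local moves until no
#' positive gain, then aggregation, repeated), applied to the undirected
#' weighted projection of the network. The seed fixes the node-visit order,
#' making the partition reproducible.
#'
#' @param network A `grn` object (non-empty).
#' @param seed Integer RNG seed (default 1).
#' @return A `grn_partition`: list with `membership` (named integer vector,
#'   0-based contiguous community ids, largest community first) and
#'   `modularity`.
#' @export
louvain_partition <- function(network, seed = 1L) {
  stopifnot(nrow(network$nodes) > 0L)
  gu <- grn_undirected(network)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(gu, weights = igraph::E(gu)$weight)
  memb <- igraph::membership(cl)
  # relabel 0-based, by decreasing community size then smallest member id
  sizes <- table(memb)
  first_id <- tapply(names(memb), as.integer(memb), min)
  ord <- order(-as.integer(sizes), first_id[names(sizes)])
  relabel <- stats::setNames(seq_along(ord) - 1L, names(sizes)[ord])
  membership <- stats::setNames(as.integer(relabel[as.character(memb)]),
                                names(memb))
  q <- igraph::modularity(gu, memb, weights = igraph::E(gu)$weight)
  structure(list(membership = membership, modularity = q),
            class = "grn_partition")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Newman-Girvan modularity of a partition
#'
#' Computed on the undirected weighted projection of the network.
#'
#' @param network A `grn` object.
#' @param membership Named vector mapping every node to a community id.
#' @return Modularity Q.
#' @export
modularity_q <- function(network, membership) {
  missing <- setdiff(network$nodes$gene_id, names(membership))
  if (length(missing)) {
    stop("partition does not cover node(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  gu <- grn_undirected(network)
  m <- membership[igraph::V(gu)$name]
  igraph::modularity(gu, as.integer(factor(m)),
                     weights = igraph::E(gu)$weight)
}

#' Community sizes, descending
#'
#' @param partition A `grn_partition` (or bare membership vector).
#' @return Integer vector of community sizes summing to the node count.
#' @export
community_sizes <- function(partition) {
  memb <- if (inherits(partition, "grn_partition")) partition$membership
          else partition
  if (!length(memb)) return(integer(0L))
  sort(as.integer(table(memb)), decreasing = TRUE)
}

#' Hypergeometric term enrichment per community
#'
#' For each (community, term) pair, a one-sided upper-tail hypergeometric
#' test of the overlap against the annotated universe (the annotated network
#' nodes), with Benjamini-Hochberg adjustment across all tests.
#'
#' @param partition A `grn_partition` or membership vector.
#' @param annotations data.frame `gene_id`, `term` (one row per
#'   gene-term assignment; genes may carry several terms).
#' @param universe Optional character vector; defaults to annotated genes
#'   that are in the partition.
#' @return data.frame `community`, `term`, `overlap`, `community_size`,
#'   `term_size`, `universe_size`, `p_value`, `p_adjust`.
#' @export
enrich_terms <- function(partition, annotations, universe = NULL) {
  memb <- if (inherits(partition, "grn_partition")) partition$membership
          else partition
  ann <- unique(annotations[, c("gene_id", "term")])
  if (is.null(universe)) {
    universe <- intersect(unique(ann$gene_id), names(memb))
  }
  if (!length(universe)) stop("empty annotation universe")
  ann <- ann[ann$gene_id %in% universe, , drop = FALSE]
  N <- length(universe)
  term_genes <- split(ann$gene_id, ann$term)
  comm_genes <- split(intersect(names(memb), universe),
                      memb[intersect(names(memb), universe)])
  rows <- list()
  for (cm in names(comm_genes)) {
    cg <- comm_genes[[cm]]
    for (tm in names(term_genes)) {
      tg <- term_genes[[tm]]
      k <- length(intersect(cg, tg))
      # P(X >= k), X ~ Hypergeom(N, |term|, |community|)
      p <- stats::phyper(k - 1L, length(tg), N - length(tg), length(cg),
                         lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        community = cm, term = tm, overlap = k,
        community_size = length(cg), term_size = length(tg),
        universe_size = N, p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Term x community enrichment matrix
#'
#' The data layer of a community-enrichment heatmap: `-log10(p_adjust)` per
#' (term, community).
#'
#' @param enrichment Output of [enrich_terms()].
#' @return Numeric matrix, terms as rows, communities as columns.
#' @export
enrichment_matrix <- function(enrichment) {
  terms <- sort(unique(enrichment$term))
  comms <- sort(unique(enrichment$community))
  mat <- matrix(0, nrow = length(terms), ncol = length(comms),
                dimnames = list(terms, comms))
  for (i in seq_len(nrow(enrichment))) {
    mat[enrichment$term[i], enrichment$community[i]] <-
      -log10(enrichment$p_adjust[i])
  }
  mat
}
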