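# Network assembly and the six-table relational store
# (gene / ortho / pwm / regulation / tfbs_prediction / network_node).
# The canonical on-disk form is a directory of six TSVs with referential
# integrity checked on save and load; re-loading reproduces the network
# exactly.

STORE_TABLES <- c("gene", "ortho", "pwm", "regulation",
                  "tfbs_prediction", "network_node")

#' Build a regulatory network from merged edges
#'
#' Node roles are derived from edge incidence: a node is a TF iff it has at
#' least one outgoing edge and a TG iff it has at least one incoming edge.
#'
#' @param edges Merged edge table ([merge_provenance()], optionally with
#'   `tfbs_count` from [count_hits_per_edge()]).
#' @return A `grn` object: list with `nodes` (data.frame `gene_id`, `is_tf`,
#'   `is_tg`) and `edges`.
#' @export
build_network <- function(edges) {
  if (nrow(edges) > 0L &&
      anyDuplicated(paste(edges$tf_id, edges$tg_id, sep = "\r"))) {
    stop("duplicate (tf, tg) pairs; merge edges with merge_provenance() first")
  }
  ids <- sort(unique(c(edges$tf_id, edges$tg_id)))
  nodes <- data.frame(gene_id = ids,
                      is_tf = ids %in% edges$tf_id,
                      is_tg = ids %in% edges$tg_id,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("Regulatory network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  cat("  TFs:", sum(x$nodes$is_tf), " TGs:", sum(x$nodes$is_tg),
      " TF-also-TG:", sum(x$nodes$is_tf & x$nodes$is_tg), "\n")
  invisible(x)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, classes = NA) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = classes)
}

#' Persist the six-table relational store
#'
#' Writes the tables `gene`, `ortho`, `pwm`, `regulation`,
#' `tfbs_prediction` and `network_node` as TSVs under `path`, after checking
#' referential integrity (edge endpoints and hit genes must exist in `gene`;
#' hit matrices must exist in `pwm`).
#'
#' @param genes Gene table ([read_genes()], any species labels appended by
#'   the caller).
#' @param orthos Ortholog pair table ([read_proteinortho()]).
#' @param pwms Named list of `FrequencyMatrix` objects or a data.frame with
#'   `matrix_id`, `tf_id`, `width`.
#' @param regulation Curated source interactions ([read_interactions()]).
#' @param hits TFBS hit table ([scan_promoters()]).
#' @param network A `grn` object ([build_network()]).
#' @param path Output directory (created if needed).
#' @return Invisibly, the list of written table paths.
#' @export
persist_store <- function(genes, orthos, pwms, regulation, hits, network,
                          path) {
  if (!is.data.frame(pwms)) {
    pwms <- data.frame(
      matrix_id = vapply(pwms, `[[`, "", "matrix_id"),
      tf_id = vapply(pwms, function(m) as.character(m$tf_id), ""),
      width = vapply(pwms, `[[`, 1L, "width"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  known_genes <- genes$gene_id
  orphan <- setdiff(c(network$edges$tf_id, network$edges$tg_id), known_genes)
  if (length(orphan)) {
    stop("network_node references unknown gene id(s): ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  }
  orphan <- setdiff(hits$gene_id, known_genes)
  if (length(orphan)) {
    stop("tfbs_prediction references unknown gene id(s): ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  }
  orphan <- setdiff(hits$matrix_id, pwms$matrix_id)
  if (length(orphan)) {
    stop("tfbs_prediction references unknown matrix id(s): ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tables <- list(gene = genes, ortho = orthos, pwm = pwms,
                 regulation = regulation, tfbs_prediction = hits,
                 network_node = network$edges)
  paths <- character(0L)
  for (nm in STORE_TABLES) {
    p <- file.path(path, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Load a persisted store
#'
#' @param path Directory written by [persist_store()].
#' @return list with the six tables plus `network` (a `grn` rebuilt from
#'   `network_node`).
#' @export
load_store <- function(path) {
  out <- list()
  for (nm in STORE_TABLES) {
    p <- file.path(path, paste0(nm, ".tsv"))
    if (!file.exists(p)) stop("store table missing: ", p)
    out[[nm]] <- read_tsv(p)
  }
  # preserve string typing for id-like columns read as other types
  for (nm in STORE_TABLES) {
    for (col in intersect(names(out[[nm]]),
                          c("gene_id", "tf_id", "tg_id", "matrix_id",
                            "provenance", "word", "contig_id", "strand",
                            "effect", "source_species", "source_protein",
                            "target_protein"))) {
      out[[nm]][[col]] <- as.character(out[[nm]][[col]])
    }
  }
  out$network <- build_network(out$network_node)
  out
}

#' Export the network edge table as TSV
#'
#' Columns `tf_id`, `tg_id`, `provenance`, `n_sources`, `effect`, `weight`,
#' `tfbs_count`, sorted by (tf, tg) for deterministic output.
#'
#' @param network A `grn` object.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
export_edge_table <- function(network, path) {
  e <- network$edges
  cols <- intersect(c("tf_id", "tg_id", "provenance", "n_sources", "effect",
                      "weight", "tfbs_count"), names(e))
  e <- e[order(e$tf_id, e$tg_id), cols, drop = FALSE]
  write_tsv(e, path)
  invisible(path)
}

#' Re-import an exported edge table
#' @param path TSV written by [export_edge_table()].
#' @return A `grn` object.
#' @export
read_edge_table <- function(path) {
  e <- read_tsv(path)
  for (col in intersect(names(e), c("tf_id", "tg_id", "provenance", "effect"))) {
    e[[col]] <- as.character(e[[col]])
  }
  build_network(e)
}

#' Summary counts in the style of the network-properties table
#'
#' @param network A `grn` object.
#' @return Named list: nodes, interactions, tfs, tgs, tf_also_tg,
#'   auto_regulations, positive/negative/unknown edge counts, and the
#'   per-provenance-category edge counts (`by_n_sources`).
#' @export
network_counts <- function(network) {
  e <- network$edges
  n <- network$nodes
  by_src <- if (nrow(e) && "n_sources" %in% names(e)) {
    tab <- table(e$n_sources)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0L)
  list(nodes = nrow(n), interactions = nrow(e),
       tfs = sum(n$is_tf), tgs = sum(n$is_tg),
       tf_also_tg = sum(n$is_tf & n$is_tg),
       auto_regulations = sum(e$tf_id == e$tg_id),
       positive = sum(e$effect == "positive"),
       negative = sum(e$effect == "negative"),
       unknown = sum(e$effect == "unknown"),
       by_n_sources = by_src)
}
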