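# Topology of the directed regulatory network: degrees, clustering,
# centralities, weak components, summary table, hub ranking.
#
# Conventions: a self-loop contributes 1 to Kin and 1 to Kout (so
# sum(K) = 2E); clustering and centralities are computed with self-loops
# removed; clustering and eigenvector centrality use the undirected simple
# projection; closeness is harmonic (well-defined on weakly connected
# digraphs); average degree is 2E/N truncated (not rounded) to one decimal.

as_igraph <- function(network, directed = TRUE) {
  e <- network$edges
  igraph::graph_from_data_frame(
    data.frame(from = e$tf_id, to = e$tg_id, stringsAsFactors = FALSE),
    directed = directed,
    vertices = network$nodes$gene_id)
}

#' Truncate to one decimal place
#' @param x Numeric.
#' @return `x` truncated towards zero at the first decimal.
#' @export
truncate1 <- function(x) trunc(x * 10 + 1e-9) / 10

#' Average total degree, 2E/N truncated to one decimal
#' @param n_edges,n_nodes Edge and node counts.
#' @return Average degree as printed in the network summary.
#' @export
average_degree <- function(n_edges, n_nodes) {
  if (n_nodes == 0L) return(0)
  truncate1(2 * n_edges / n_nodes)
}

#' Hub out-degree as an integer percentage of nodes
#' @param kout_max Maximum out-degree.
#' @param n_nodes Node count.
#' @return `trunc(100 * kout_max / n_nodes)`.
#' @export
hub_percentage <- function(kout_max, n_nodes) {
  if (n_nodes == 0L) return(0L)
  as.integer(trunc(100 * kout_max / n_nodes + 1e-9))
}

#' Per-node in/out/total degrees
#'
#' @param network A `grn` object.
#' @return data.frame `gene_id`, `kin`, `kout`, `k` with
#'   `sum(k) == 2 * n_edges`.
#' @export
degrees <- function(network) {
  g <- as_igraph(network)
  data.frame(gene_id = network$nodes$gene_id,
             kin = as.integer(igraph::degree(g, mode = "in", loops = TRUE)),
             kout = as.integer(igraph::degree(g, mode = "out", loops = TRUE)),
             k = as.integer(igraph::degree(g, mode = "all", loops = TRUE)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-node clustering coefficients
#'
#' Computed on the undirected simple projection with self-loops removed;
#' nodes of projected degree < 2 get coefficient 0.
#'
#' @param network A `grn` object.
#' @return Named numeric vector in `[0, 1]`.
#' @export
clustering_coefficients <- function(network) {
  if (nrow(network$nodes) == 0L) return(stats::setNames(numeric(0L), NULL))
  g <- igraph::simplify(igraph::as_undirected(as_igraph(network),
                                              mode = "collapse"))
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  stats::setNames(cc, igraph::V(g)$name)[network$nodes$gene_id]
}

#' Node centralities
#'
#' Degree and betweenness on the directed graph (self-loops removed),
#' closeness as harmonic centrality on the directed graph (defined even with
#' unreachable pairs), eigenvector centrality on the undirected simple
#' projection, normalized to unit maximum.
#'
#' @param network A `grn` object.
#' @return data.frame `gene_id`, `degree`, `closeness`, `betweenness`,
#'   `eigenvector`.
#' @export
centralities <- function(network) {
  g <- as_igraph(network)
  g <- igraph::simplify(g, remove.multiple = FALSE, remove.loops = TRUE)
  gu <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  # ARPACK draws its starting vector from the RNG; pin it so repeated runs
  # are bit-identical, and restore the caller's RNG state
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(0L)
  ev <- igraph::eigen_centrality(gu)$vector
  data.frame(
    gene_id = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g, mode = "all")),
    closeness = as.numeric(igraph::harmonic_centrality(g, mode = "out")),
    betweenness = as.numeric(igraph::betweenness(g, directed = TRUE)),
    eigenvector = as.numeric(ev[igraph::V(g)$name]),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Weakly connected components
#'
#' @param network A `grn` object.
#' @return List of character vectors of node ids, sorted by decreasing size.
#' @export
weak_components <- function(network) {
  if (nrow(network$nodes) == 0L) return(list())
  g <- as_igraph(network)
  comp <- igraph::components(g, mode = "weak")
  parts <- split(igraph::V(g)$name, comp$membership)
  parts <- unname(lapply(parts, sort))
  parts[order(-vapply(parts, length, 1L))]
}

#' Hub ranking by out-degree
#'
#' @param network A `grn` object.
#' @param n Number of hubs to return (default 10; fewer if the network has
#'   fewer TFs).
#' @return data.frame `tf_id`, `kout`, descending `kout` with lexicographic
#'   id tie-break.
#' @export
top_hubs <- function(network, n = 10L) {
  stopifnot(n >= 1L)
  d <- degrees(network)
  d <- d[d$kout > 0L, , drop = FALSE]
  d <- d[order(-d$kout, d$gene_id), , drop = FALSE]
  d <- utils::head(d, n)
  data.frame(tf_id = d$gene_id, kout = d$kout,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Network summary in the style of the paper-level properties table
#'
#' @param network A `grn` object.
#' @return Named list: `nodes`, `interactions`, `auto_regulations`,
#'   `positive`, `negative`, `unknown`, `average_degree`,
#'   `connected_components`, `giant_component`, `max_out_degree`,
#'   `max_out_node`, `max_in_degree`, `max_in_node`,
#'   `average_clustering`, `hub_percentage`.
#' @export
summarize_topology <- function(network) {
  cnt <- network_counts(network)
  if (cnt$nodes == 0L) {
    return(list(nodes = 0L, interactions = 0L, auto_regulations = 0L,
                positive = 0L, negative = 0L, unknown = 0L,
                average_degree = 0, connected_components = 0L,
                giant_component = 0L, max_out_degree = 0L,
                max_out_node = NA_character_, max_in_degree = 0L,
                max_in_node = NA_character_, average_clustering = 0,
                hub_percentage = 0L))
  }
  d <- degrees(network)
  comps <- weak_components(network)
  io <- which.max(d$kout)
  ii <- which.max(d$kin)
  list(nodes = cnt$nodes, interactions = cnt$interactions,
       auto_regulations = cnt$auto_regulations,
       positive = cnt$positive, negative = cnt$negative,
       unknown = cnt$unknown,
       average_degree = average_degree(cnt$interactions, cnt$nodes),
       connected_components = length(comps),
       giant_component = length(comps[[1L]]),
       max_out_degree = d$kout[io], max_out_node = d$gene_id[io],
       max_in_degree = d$kin[ii], max_in_node = d$gene_id[ii],
       average_clustering = mean(clustering_coefficients(network)),
       hub_percentage = hub_percentage(d$kout[io], cnt$nodes))
}
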