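# Orthology-based transfer of curated TF->TG regulatory interactions from
# model species to a target species.
#
# Transfer rule: a new TF->TG edge is created in the target species only when
# orthologs exist for BOTH the TF and the TG; many-to-many orthology is
# expanded as a full cross-product, with source-species provenance retained
# on every edge.

#' Read an ortholog table in ProteinOrtho layout
#'
#' Expected layout: a header row (`# Species  Genes  Alg.-Conn.  <sp1> ...`),
#' then one row per ortholog group with comma-separated co-orthologs per
#' species column and `*` marking absence.
#'
#' @param tsv_path Path to the tab-delimited ortholog table.
#' @param target_species Column name of the target species.
#' @param source_species_list Character vector of source-species column names.
#' @return data.frame with columns `source_species`, `source_protein`,
#'   `target_protein`, `group_id` (one row per source/target protein pair;
#'   pairs from one table row share `group_id`).
#' @export
read_proteinortho <- function(tsv_path, target_species, source_species_list) {
  lines <- readLines(tsv_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty ortholog table: ", tsv_path)
  header <- strsplit(sub("^#\\s*", "", lines[1L]), "\t")[[1L]]
  for (sp in c(target_species, source_species_list)) {
    if (!sp %in% header) {
      stop("species column '", sp, "' not found in ", tsv_path)
    }
  }
  if (length(lines) == 1L) {
    return(data.frame(source_species = character(),
                      source_protein = character(),
                      target_protein = character(),
                      group_id = integer(), stringsAsFactors = FALSE))
  }
  rows <- strsplit(lines[-1L], "\t")
  tgt_col <- match(target_species, header)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    tgt <- r[tgt_col]
    if (is.na(tgt) || tgt == "*" || tgt == "") next
    tgt_prots <- strsplit(tgt, ",", fixed = TRUE)[[1L]]
    per_sp <- list()
    for (sp in source_species_list) {
      v <- r[match(sp, header)]
      if (is.na(v) || v == "*" || v == "") next
      src_prots <- strsplit(v, ",", fixed = TRUE)[[1L]]
      per_sp[[sp]] <- expand.grid(source_protein = src_prots,
                                  target_protein = tgt_prots,
                                  stringsAsFactors = FALSE)
    }
    if (length(per_sp)) {
      df <- do.call(rbind, Map(function(sp, d) {
        cbind(source_species = sp, d, stringsAsFactors = FALSE)
      }, names(per_sp), per_sp))
      df$group_id <- i
      out[[i]] <- df
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(source_species = character(),
                      source_protein = character(),
                      target_protein = character(),
                      group_id = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  unique(res)
}

#' Read a curated regulatory-interaction table
#'
#' Tab-delimited with columns `tf_id`, `tg_id` and optionally `effect`
#' (positive / negative / unknown, any case). When a reference gene list is
#' supplied, interactions whose TF or TG is not in the list are dropped with
#' a warning (curation cross-validation).
#'
#' @param tsv_path Path to the interaction TSV.
#' @param species Source-species label attached to every interaction.
#' @param gene_list Optional character vector of valid gene ids.
#' @return data.frame `source_species`, `tf_id`, `tg_id`, `effect`
#'   (deduplicated).
#' @export
read_interactions <- function(tsv_path, species, gene_list = NULL) {
  d <- utils::read.delim(tsv_path, header = TRUE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("tf_id", "tg_id") %in% names(d))) {
    stop("interaction table must have columns 'tf_id' and 'tg_id': ", tsv_path)
  }
  effect <- if ("effect" %in% names(d)) tolower(d$effect) else
    rep("unknown", nrow(d))
  effect[is.na(effect) | !(effect %in% c("positive", "negative"))] <- "unknown"
  out <- data.frame(source_species = species, tf_id = d$tf_id,
                    tg_id = d$tg_id, effect = effect,
                    stringsAsFactors = FALSE)
  if (!is.null(gene_list)) {
    ok <- out$tf_id %in% gene_list & out$tg_id %in% gene_list
    if (any(!ok)) {
      bad <- out[!ok, , drop = FALSE]
      warning(sum(!ok), " interaction(s) discarded for ", species,
              ": gene(s) absent from the reference gene list (e.g. ",
              paste(utils::head(unique(c(
                bad$tf_id[!bad$tf_id %in% gene_list],
                bad$tg_id[!bad$tg_id %in% gene_list])), 3L),
                collapse = ", "), ")")
      out <- out[ok, , drop = FALSE]
    }
  }
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Transfer curated interactions to the target species through orthology
#'
#' For each source interaction, every pair in
#' `orthologs(TF) x orthologs(TG)` becomes a candidate edge in the target
#' species; nothing is emitted when either side lacks an ortholog. Edges are
#' NOT merged here (see [merge_provenance()]), so the per-source provenance
#' of each candidate edge is preserved.
#'
#' @param interactions data.frame from [read_interactions()] (possibly
#'   several species row-bound).
#' @param ortholog_pairs data.frame from [read_proteinortho()].
#' @param target_species Target species label (annotation only).
#' @return data.frame `tf_id`, `tg_id` (target ids), `source_species`,
#'   `effect`, deduplicated per (tf, tg, species).
#' @export
transfer_interactions <- function(interactions, ortholog_pairs,
                                  target_species = "target") {
  if (nrow(interactions) == 0L) {
    return(data.frame(tf_id = character(), tg_id = character(),
                      source_species = character(), effect = character(),
                      stringsAsFactors = FALSE))
  }
  key <- function(sp, prot) paste(sp, prot, sep = "\r")
  orth_map <- split(ortholog_pairs$target_protein,
                    key(ortholog_pairs$source_species,
                        ortholog_pairs$source_protein))
  out <- vector("list", nrow(interactions))
  for (i in seq_len(nrow(interactions))) {
    sp <- interactions$source_species[i]
    tf_orth <- orth_map[[key(sp, interactions$tf_id[i])]]
    tg_orth <- orth_map[[key(sp, interactions$tg_id[i])]]
    if (is.null(tf_orth) || is.null(tg_orth)) next
    g <- expand.grid(tf_id = unique(tf_orth), tg_id = unique(tg_orth),
                     stringsAsFactors = FALSE)
    g$source_species <- sp
    g$effect <- interactions$effect[i]
    out[[i]] <- g
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(tf_id = character(), tg_id = character(),
                      source_species = character(), effect = character(),
                      stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  attr(res, "target_species") <- target_species
  res
}

# Resolve effect signs across supporting records: agreeing signs keep the
# sign, a sign beats "unknown", conflicting signs give "unknown".
resolve_effect <- function(effects) {
  signs <- unique(effects[effects %in% c("positive", "negative")])
  if (length(signs) == 1L) signs else "unknown"
}

#' Merge transferred edges by (TF, TG), accumulating provenance and weight
#'
#' Identical pairs are collapsed; `provenance` is the union of supporting
#' source species (canonically ordered); `effect` is the common sign if all
#' signed supports agree (a sign beats "unknown"), else "unknown"; `weight`
#' is the sum of the per-species weights (default 1 each, so weight = number
#' of supporting species; a phylogenetic-distance scheme can be supplied).
#'
#' @param edges data.frame from [transfer_interactions()].
#' @param weight_scheme Named numeric vector of positive per-species weights;
#'   `NULL` gives every species weight 1.
#' @param species_order Canonical species order for provenance labels;
#'   defaults to sorted unique species in `edges` (or `weight_scheme` names).
#' @return data.frame `tf_id`, `tg_id`, `provenance` (semicolon-joined),
#'   `n_sources`, `effect`, `weight`, `tfbs_count` (NA, filled by
#'   [count_hits_per_edge()]), sorted by (tf_id, tg_id).
#' @export
merge_provenance <- function(edges, weight_scheme = NULL,
                             species_order = NULL) {
  species_seen <- unique(edges$source_species)
  if (is.null(species_order)) {
    species_order <- if (!is.null(weight_scheme)) names(weight_scheme) else
      sort(species_seen)
  }
  if (is.null(weight_scheme)) {
    weight_scheme <- stats::setNames(rep(1, length(species_order)),
                                     species_order)
  }
  unknown <- setdiff(species_seen, names(weight_scheme))
  if (length(unknown)) {
    stop("species without a weight in weight_scheme: ",
         paste(unknown, collapse = ", "))
  }
  if (any(weight_scheme <= 0)) stop("weights must be positive")
  if (nrow(edges) == 0L) {
    return(data.frame(tf_id = character(), tg_id = character(),
                      provenance = character(), n_sources = integer(),
                      effect = character(), weight = numeric(),
                      tfbs_count = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(edges$tf_id, edges$tg_id, sep = "\r")
  idx <- split(seq_len(nrow(edges)), key)
  rows <- lapply(idx, function(i) {
    sp <- unique(edges$source_species[i])
    sp <- species_order[species_order %in% sp]
    data.frame(tf_id = edges$tf_id[i[1L]], tg_id = edges$tg_id[i[1L]],
               provenance = paste(sp, collapse = ";"),
               n_sources = length(sp),
               effect = resolve_effect(edges$effect[i]),
               weight = sum(weight_scheme[sp]),
               tfbs_count = NA_integer_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$tf_id, out$tg_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
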