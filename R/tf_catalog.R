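# Transcription-factor classification: match per-protein PFAM / InterPro
# domain annotations against a catalog of eukaryotic DNA-binding-domain
# families and summarise the TFome.

#' Load a TF DNA-binding-domain family catalog
#'
#' The catalog is a two-column TSV (`family`, `accession`) mapping family
#' names to PFAM (`PFxxxxx`) and InterPro (`IPRxxxxxx`) accessions. The
#' packaged default covers the 37 families commonly recovered from fungal
#' proteomes; it is a plain TSV and can be extended or replaced. The order
#' of first appearance of families defines the canonical family order used
#' for multi-domain combination labels.
#'
#' @param tsv_path Path to a catalog TSV; `NULL` loads the packaged default.
#' @return data.frame (`family`, `accession`) with attribute
#'   `family_order`; duplicated identical rows are collapsed.
#' @export
load_catalog <- function(tsv_path = NULL) {
  if (is.null(tsv_path)) {
    tsv_path <- system.file("extdata", "tf_family_catalog.tsv",
                            package = "funregnet", mustWork = TRUE)
  }
  cat_df <- utils::read.delim(tsv_path, header = TRUE,
                              stringsAsFactors = FALSE,
                              colClasses = "character")
  if (!all(c("family", "accession") %in% names(cat_df))) {
    stop("catalog must have columns 'family' and 'accession'")
  }
  cat_df <- unique(cat_df[, c("family", "accession")])
  dup <- duplicated(cat_df$accession)
  if (any(dup)) {
    stop("accession(s) mapped to more than one family: ",
         paste(unique(cat_df$accession[dup]), collapse = ", "))
  }
  if (nrow(cat_df) == 0L) stop("empty catalog: ", tsv_path)
  attr(cat_df, "family_order") <- unique(cat_df$family)
  class(cat_df) <- c("tf_catalog", "data.frame")
  cat_df
}

#' Assign proteins to TF families from their domain annotations
#'
#' PFAM and InterPro evidence is unioned: a catalog accession hit from either
#' source suffices. Proteins without any catalog hit are absent from the
#' output. Families are ordered by the catalog's canonical family order so
#' multi-domain combination labels (e.g. `"Zn2Cys6+C2H2_ZF"`) are
#' deterministic.
#'
#' @param annotations data.frame with columns `protein_id`, `accession`
#'   (and optionally `source_db`; unknown accessions are ignored).
#' @param catalog A catalog from [load_catalog()].
#' @return data.frame with columns `protein_id`, `combo_label`, `n_families`
#'   and a list-column `families`.
#' @export
assign_families <- function(annotations, catalog) {
  fam_of <- stats::setNames(catalog$family, catalog$accession)
  fam_order <- attr(catalog, "family_order")
  hit <- annotations$accession %in% names(fam_of)
  ann <- annotations[hit, , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(data.frame(protein_id = character(), combo_label = character(),
                      n_families = integer(), stringsAsFactors = FALSE,
                      families = I(list())))
  }
  fams_by_protein <- tapply(unname(fam_of[ann$accession]), ann$protein_id,
                            function(f) fam_order[fam_order %in% f],
                            simplify = FALSE)
  ids <- sort(names(fams_by_protein))
  fams <- fams_by_protein[ids]
  out <- data.frame(protein_id = ids,
                    combo_label = vapply(fams, paste, "", collapse = "+"),
                    n_families = vapply(fams, length, 1L),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$families <- I(unname(fams))
  out
}

#' Tally TF families across species
#'
#' A multi-domain protein is counted once under each member family in the
#' count matrix, and once under its exact combination in the combo table
#' (so the combo table totals the number of multi-family proteins).
#'
#' @param assignments_by_species Named list of [assign_families()] outputs,
#'   one per species.
#' @return list with `matrix` (family x species counts, only families seen
#'   at least once) and `combos` (data.frame `species`, `combo_label`,
#'   `count` for multi-family proteins).
#' @export
family_count_matrix <- function(assignments_by_species) {
  stopifnot(length(assignments_by_species) >= 1L)
  species <- names(assignments_by_species)
  all_fams <- unique(unlist(lapply(assignments_by_species, function(a) {
    unlist(a$families)
  })))
  mat <- matrix(0L, nrow = length(all_fams), ncol = length(species),
                dimnames = list(all_fams, species))
  combos <- list()
  for (sp in species) {
    a <- assignments_by_species[[sp]]
    if (is.null(a) || nrow(a) == 0L) next
    tab <- table(unlist(a$families))
    mat[names(tab), sp] <- as.integer(tab)
    multi <- a[a$n_families > 1L, , drop = FALSE]
    if (nrow(multi)) {
      ct <- table(multi$combo_label)
      combos[[sp]] <- data.frame(species = sp, combo_label = names(ct),
                                 count = as.integer(ct),
                                 stringsAsFactors = FALSE)
    }
  }
  combos <- if (length(combos)) {
    do.call(rbind, c(combos, list(make.row.names = FALSE)))
  } else {
    data.frame(species = character(), combo_label = character(),
               count = integer(), stringsAsFactors = FALSE)
  }
  list(matrix = mat, combos = combos)
}
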