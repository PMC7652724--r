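# Seed-reproducible synthetic input bundles with planted ground truth.
#
# A fixture emulates every input the pipeline consumes: a target genome
# (FASTA + GFF3) whose promoters are i.i.d. under a stated 0-order
# background, per-species curated interaction tables, a ProteinOrtho-layout
# ortholog table, CIS-BP motif matrices, per-protein domain annotations and
# a gene->term table. True-edge target promoters carry planted
# near-consensus motif instances at recorded offsets, so edge transfer and
# binding-site recovery can be checked against exact ground truth.

FIXTURE_SPECIES <- c("Anidulans", "Ncrassa", "Scerevisiae")
FIXTURE_BG <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)

#' Fixture configuration
#'
#' @param seed RNG seed; the bundle is a pure function of the full config.
#' @param n_target_genes Number of gene families (one target gene each, plus
#'   occasional co-orthologs).
#' @param n_source_species Number of source species (max 3 named model
#'   fungi).
#' @param n_interactions Curated interactions per source species.
#' @param n_tfs Number of TF families (regulator side of interactions).
#' @param orthology_rate Fraction of families with a target ortholog.
#' @param co_ortholog_rate Fraction of ortholog families with 2 target
#'   co-orthologs.
#' @param motif_width Motif width in bp.
#' @param plant_rate Fraction of true edges whose target promoter receives a
#'   planted consensus site.
#' @param promoter_length Promoter length in bp (default 1000).
#' @param effect_mix Named proportions for positive/negative/unknown effects
#'   (must sum to 1).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_target_genes = 60L,
                           n_source_species = 3L, n_interactions = 40L,
                           n_tfs = 6L, orthology_rate = 0.8,
                           co_ortholog_rate = 0.1, motif_width = 9L,
                           plant_rate = 0.9, promoter_length = 1000L,
                           effect_mix = c(positive = 0.4, negative = 0.25,
                                          unknown = 0.35)) {
  stopifnot(n_target_genes >= 1L, n_source_species >= 1L,
            n_source_species <= length(FIXTURE_SPECIES),
            n_interactions >= 1L, n_tfs >= 1L, n_tfs <= n_target_genes,
            orthology_rate >= 0, orthology_rate <= 1,
            co_ortholog_rate >= 0, co_ortholog_rate <= 1,
            plant_rate >= 0, plant_rate <= 1,
            motif_width >= 1L, promoter_length >= 1L,
            abs(sum(effect_mix) - 1) < 1e-9)
  if (motif_width > promoter_length) {
    stop("motif_width must not exceed promoter_length")
  }
  structure(list(seed = as.integer(seed),
                 n_target_genes = as.integer(n_target_genes),
                 n_source_species = as.integer(n_source_species),
                 n_interactions = as.integer(n_interactions),
                 n_tfs = as.integer(n_tfs),
                 orthology_rate = orthology_rate,
                 co_ortholog_rate = co_ortholog_rate,
                 motif_width = as.integer(motif_width),
                 plant_rate = plant_rate,
                 promoter_length = as.integer(promoter_length),
                 effect_mix = effect_mix),
            class = "fixture_config")
}

rand_dna <- function(n, bg = FIXTURE_BG) {
  paste(sample(names(bg), n, replace = TRUE, prob = bg), collapse = "")
}

fixture_id_of <- function(config) {
  paste0("fx-", paste(unlist(config), collapse = "-"))
}

#' Generate a synthetic input bundle with planted ground truth
#'
#' Writes `genome.fa`, `genes.gff3`, `ortho.tsv` (ProteinOrtho layout),
#' `interactions_<species>.tsv`, `matrices/M*.txt` (CIS-BP layout),
#' `matrix_tf_map.tsv`, `domains.tsv` and `terms.tsv` under `out_dir`, and
#' returns the file map together with the planted `truth`:
#' the merged edge set the transfer rule must produce, and the planted
#' binding-site locations per promoter.
#'
#' @param config A [fixture_config()].
#' @param out_dir Output directory (created; overwritten if existing).
#' @return list with `paths`, `truth` (`edges`, `planted_hits`,
#'   `background_genes`), `config`, `species`, `fixture_id`.
#' @export
generate_fixture <- function(config, out_dir) {
  stopifnot(inherits(config, "fixture_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "matrices"), showWarnings = FALSE)

  species <- FIXTURE_SPECIES[seq_len(config$n_source_species)]
  nfam <- config$n_target_genes
  fam_ids <- seq_len(nfam)
  src_gene <- function(sp, fam) sprintf("%s_g%03d", sp, fam)

  # --- orthology: which families have target orthologs (and co-orthologs)
  has_orth <- stats::runif(nfam) < config$orthology_rate
  has_co <- has_orth & (stats::runif(nfam) < config$co_ortholog_rate)
  target_orths <- lapply(fam_ids, function(f) {
    if (!has_orth[f]) character(0L)
    else if (has_co[f]) sprintf("TGT_%04d%s", f, c("", "b"))
    else sprintf("TGT_%04d", f)
  })
  target_genes <- unlist(target_orths)

  # --- ProteinOrtho-layout table
  n_in_row <- vapply(target_orths, length, 1L) + length(species)
  ortho_lines <- c(
    paste(c("# Species", "Genes", "Alg.-Conn.", species, "Target"),
          collapse = "\t"),
    vapply(fam_ids, function(f) {
      paste(c(length(species) + as.integer(has_orth[f]), n_in_row[f], "1",
              vapply(species, src_gene, "", fam = f),
              if (has_orth[f]) paste(target_orths[[f]], collapse = ",")
              else "*"),
            collapse = "\t")
    }, "")
  )

  # --- curated interactions per species (TF families regulate any family)
  interactions <- list()
  for (sp in species) {
    tf_fam <- sample(seq_len(config$n_tfs), config$n_interactions,
                     replace = TRUE)
    tg_fam <- sample(fam_ids, config$n_interactions, replace = TRUE)
    eff <- sample(names(config$effect_mix), config$n_interactions,
                  replace = TRUE, prob = config$effect_mix)
    d <- unique(data.frame(tf_fam = tf_fam, tg_fam = tg_fam, effect = eff,
                           stringsAsFactors = FALSE))
    d <- d[!duplicated(d[, c("tf_fam", "tg_fam")]), , drop = FALSE]
    interactions[[sp]] <- d
  }

  # --- ground-truth merged edges: plain cross-product transfer + merge
  raw <- list()
  for (sp in species) {
    d <- interactions[[sp]]
    for (i in seq_len(nrow(d))) {
      tfs <- target_orths[[d$tf_fam[i]]]
      tgs <- target_orths[[d$tg_fam[i]]]
      if (!length(tfs) || !length(tgs)) next
      for (a in tfs) for (b in tgs) {
        raw[[length(raw) + 1L]] <- data.frame(
          tf_id = a, tg_id = b, source_species = sp,
          effect = d$effect[i], stringsAsFactors = FALSE)
      }
    }
  }
  truth_edges <- if (length(raw)) {
    rawdf <- unique(do.call(rbind, raw))
    keys <- unique(paste(rawdf$tf_id, rawdf$tg_id, sep = "\r"))
    rows <- lapply(keys, function(k) {
      sub <- rawdf[paste(rawdf$tf_id, rawdf$tg_id, sep = "\r") == k, ]
      sp <- species[species %in% sub$source_species]
      data.frame(tf_id = sub$tf_id[1L], tg_id = sub$tg_id[1L],
                 provenance = paste(sp, collapse = ";"),
                 n_sources = length(sp),
                 effect = resolve_effect(sub$effect),
                 weight = length(sp), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$tf_id, out$tg_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(tf_id = character(), tg_id = character(),
               provenance = character(), n_sources = integer(),
               effect = character(), weight = numeric(),
               stringsAsFactors = FALSE)
  }

  # --- motifs: one near-consensus matrix per TF family with an ortholog
  L <- config$promoter_length
  w <- config$motif_width
  motifs <- list()
  matrix_tf <- character(0L)
  for (f in seq_len(config$n_tfs)) {
    if (!has_orth[f]) next
    mid <- sprintf("M%03d_2.00", f)
    consensus <- strsplit(rand_dna(w, c(A = .25, C = .25, G = .25, T = .25)),
                          "")[[1L]]
    probs <- matrix(0.01, nrow = w, ncol = 4L,
                    dimnames = list(NULL, c("A", "C", "G", "T")))
    for (i in seq_len(w)) probs[i, consensus[i]] <- 0.97
    motifs[[mid]] <- list(consensus = paste(consensus, collapse = ""),
                          probs = probs,
                          tf_id = target_orths[[f]][1L])
    matrix_tf[mid] <- target_orths[[f]][1L]
  }

  # --- promoters (oriented), with planted sites on true-edge targets
  promoters <- stats::setNames(
    vapply(target_genes, function(g) rand_dna(L), ""), target_genes)
  planted_slots <- stats::setNames(
    lapply(target_genes, function(g) matrix(0L, 0L, 2L)), target_genes)
  planted <- list()
  tf_matrix <- if (length(matrix_tf)) {
    stats::setNames(names(matrix_tf), matrix_tf)  # tf -> matrix
  } else character(0L)
  if (nrow(truth_edges)) {
    for (i in seq_len(nrow(truth_edges))) {
      tf <- truth_edges$tf_id[i]
      tg <- truth_edges$tg_id[i]
      mid <- tf_matrix[tf]
      if (is.na(mid)) next
      if (stats::runif(1L) >= config$plant_rate) next
      slots <- planted_slots[[tg]]
      off <- NA_integer_
      for (try in seq_len(50L)) {
        cand <- sample.int(L - w + 1L, 1L) - 1L
        clash <- any(cand < slots[, 2L] & (cand + w) > slots[, 1L])
        if (!clash) { off <- cand; break }
      }
      if (is.na(off)) next
      word <- motifs[[mid]]$consensus
      substr(promoters[[tg]], off + 1L, off + w) <- word
      planted_slots[[tg]] <- rbind(slots, c(off, off + w))
      planted[[length(planted) + 1L]] <- data.frame(
        gene_id = tg, matrix_id = unname(mid), offset = off, strand = "+",
        word = word, stringsAsFactors = FALSE)
    }
  }
  planted_hits <- if (length(planted)) {
    p <- do.call(rbind, planted)
    p <- p[order(p$gene_id, p$matrix_id, p$offset), , drop = FALSE]
    rownames(p) <- NULL
    p
  } else {
    data.frame(gene_id = character(), matrix_id = character(),
               offset = integer(), strand = character(), word = character(),
               stringsAsFactors = FALSE)
  }

  # --- genome layout: per-gene blocks of [spacer][promoter][body] on
  #     contigs of up to 8 genes; '-' strand genes store the reverse
  #     complement of their promoter downstream of the body
  body_len <- 120L
  spacer <- 40L
  strands <- sample(c("+", "-"), length(target_genes), replace = TRUE)
  contigs <- list()
  gff <- character(0L)
  per_contig <- 8L
  for (ci in seq_len(ceiling(length(target_genes) / per_contig))) {
    idx <- ((ci - 1L) * per_contig + 1L):min(ci * per_contig,
                                             length(target_genes))
    ctg <- sprintf("ctg%02d", ci)
    pieces <- character(0L)
    pos <- 0L
    for (j in idx) {
      g <- target_genes[j]
      body <- rand_dna(body_len)
      if (strands[j] == "+") {
        block <- paste0(rand_dna(spacer), promoters[[g]], body)
        gstart <- pos + spacer + L + 1L
      } else {
        block <- paste0(rand_dna(spacer), body, revcomp(promoters[[g]]))
        gstart <- pos + spacer + 1L
      }
      gend <- gstart + body_len - 1L
      gff <- c(gff, paste(ctg, "synthetic", "gene", gstart, gend, ".",
                          strands[j], ".", paste0("ID=", g), sep = "\t"))
      pieces <- c(pieces, block)
      pos <- pos + nchar(block)
    }
    contigs[[ctg]] <- paste(pieces, collapse = "")
  }

  # --- write the bundle
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    gff3 = file.path(out_dir, "genes.gff3"),
    ortho = file.path(out_dir, "ortho.tsv"),
    matrix_dir = file.path(out_dir, "matrices"),
    matrix_tf_map = file.path(out_dir, "matrix_tf_map.tsv"),
    domains = file.path(out_dir, "domains.tsv"),
    terms = file.path(out_dir, "terms.tsv"))
  fa <- character(0L)
  for (ctg in names(contigs)) {
    fa <- c(fa, paste0(">", ctg), gsub("(.{70})", "\\1\n", contigs[[ctg]]))
  }
  writeLines(fa, paths$genome)
  writeLines(c("##gff-version 3", gff), paths$gff3)
  writeLines(ortho_lines, paths$ortho)
  for (sp in species) {
    p <- file.path(out_dir, paste0("interactions_", sp, ".tsv"))
    d <- interactions[[sp]]
    writeLines(c("tf_id\ttg_id\teffect",
                 sprintf("%s\t%s\t%s", src_gene(sp, d$tf_fam),
                         src_gene(sp, d$tg_fam), d$effect)), p)
    paths[[paste0("interactions_", sp)]] <- p
  }
  for (mid in names(motifs)) {
    m <- motifs[[mid]]
    lines <- c("Pos\tA\tC\tG\tT",
               vapply(seq_len(w), function(i) {
                 paste(c(i, format(m$probs[i, ], nsmall = 2L)),
                       collapse = "\t")
               }, ""))
    writeLines(lines, file.path(paths$matrix_dir, paste0(mid, ".txt")))
  }
  writeLines(c("matrix_id\ttf_id",
               sprintf("%s\t%s", names(matrix_tf), matrix_tf)),
             paths$matrix_tf_map)
  # domain annotations: TF targets get a Zn2Cys6 accession, others a kinase
  tf_targets <- unique(stats::na.omit(unname(matrix_tf)))
  dom <- data.frame(protein_id = target_genes,
                    accession = ifelse(target_genes %in% tf_targets,
                                       "PF00172", "PF00069"),
                    source_db = rep("PFAM", length(target_genes)),
                    stringsAsFactors = FALSE)
  writeLines(c("protein_id\taccession\tsource_db",
               sprintf("%s\t%s\t%s", dom$protein_id, dom$accession,
                       dom$source_db)), paths$domains)
  # flat term annotations: random terms, plus one term concentrated on the
  # regulon of the most connected TF (signal for enrichment tests)
  terms_pool <- sprintf("GO:%07d", 1:8)
  ann <- data.frame(gene_id = target_genes,
                    term = sample(terms_pool, length(target_genes),
                                  replace = TRUE),
                    stringsAsFactors = FALSE)
  if (nrow(truth_edges)) {
    big_tf <- names(sort(table(truth_edges$tf_id), decreasing = TRUE))[1L]
    regulon <- truth_edges$tg_id[truth_edges$tf_id == big_tf]
    if (length(regulon) >= 3L) {
      ann <- rbind(ann, data.frame(gene_id = regulon, term = "GO:9999999",
                                   stringsAsFactors = FALSE))
    }
  }
  ann <- unique(ann[order(ann$gene_id, ann$term), , drop = FALSE])
  writeLines(c("gene_id\tterm",
               sprintf("%s\t%s", ann$gene_id, ann$term)), paths$terms)

  bg_genes <- setdiff(target_genes, unique(truth_edges$tg_id))
  list(paths = paths,
       truth = list(edges = truth_edges, planted_hits = planted_hits,
                    background_genes = bg_genes,
                    fixture_id = fixture_id_of(config)),
       config = config, species = species,
       fixture_id = fixture_id_of(config))
}

#' Compare pipeline outputs against planted ground truth
#'
#' Edge precision/recall/F1 compare the merged edge set (tf, tg, provenance,
#' effect) against the planted edges; planted-hit recall is the fraction of
#' planted sites recovered at matching (gene, matrix, offset, strand);
#' the background false-hit rate is measured on promoters of genes that are
#' not targets of any true edge and compared with the
#' `2 * (L - w + 1) * p_threshold` expectation, with a binomial 95% CI.
#'
#' @param outputs list with `edges` (merged edge table) and `hits` (hit
#'   table), plus `fixture_id` (optional but checked when present).
#' @param truth The `truth` element returned by [generate_fixture()].
#' @param config The fixture config (for promoter length / motif width).
#' @param p_threshold Scan threshold used to produce `hits`.
#' @return list of evaluation metrics.
#' @export
evaluate_against_truth <- function(outputs, truth, config,
                                   p_threshold = 1e-4) {
  if (!is.null(outputs$fixture_id) &&
      !identical(outputs$fixture_id, truth$fixture_id)) {
    stop("outputs and truth come from different fixtures")
  }
  ekey <- function(d) paste(d$tf_id, d$tg_id, d$provenance, d$effect,
                            sep = "\r")
  got <- ekey(outputs$edges)
  want <- ekey(truth$edges)
  tp <- length(intersect(got, want))
  precision <- if (length(got)) tp / length(got) else 1
  recall <- if (length(want)) tp / length(want) else 1
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  hkey <- function(d) paste(d$gene_id, d$matrix_id, d$offset, d$strand,
                            sep = "\r")
  ph <- truth$planted_hits
  hit_recall <- if (nrow(ph)) {
    mean(hkey(ph) %in% hkey(outputs$hits))
  } else NA_real_
  L <- config$promoter_length
  w <- config$motif_width
  bg <- truth$background_genes
  n_windows <- 2 * (L - w + 1) * length(bg)
  n_false <- sum(outputs$hits$gene_id %in% bg)
  rate <- if (n_windows > 0) n_false / n_windows else NA_real_
  ci <- if (n_windows > 0) {
    as.numeric(stats::binom.test(n_false, n_windows)$conf.int)
  } else c(NA_real_, NA_real_)
  list(edge_precision = precision, edge_recall = recall, edge_f1 = f1,
       planted_hit_recall = hit_recall,
       false_hit_rate = rate, false_hit_ci = ci,
       expected_false_rate = p_threshold,
       n_false_hits = n_false, n_background_windows = n_windows)
}
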