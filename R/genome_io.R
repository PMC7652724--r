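# Genome and annotation I/O: FASTA genomes, GFF3 gene models, strand-aware
# promoter extraction.
#
# Coordinate conventions (stated once, used everywhere):
#   * GFF3 gene records are 1-based inclusive, as in the format itself.
#   * Promoter intervals are 0-based half-open genomic intervals; the
#     PromoterRecord sequence is oriented 5'->3' relative to the gene.

#' Read a genome FASTA file
#'
#' Contig identifiers are taken from the first whitespace-delimited token of
#' each header. Sequences are upper-cased; IUPAC ambiguity codes such as `N`
#' are kept verbatim.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A named character vector (one element per contig, upper-case).
#' @export
read_genome <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) {
    stop("empty FASTA file: ", fasta_path)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate contig id(s) in ", fasta_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genome <- toupper(as.character(seqs))
  names(genome) <- ids
  genome
}

#' Read gene records from a GFF3 file
#'
#' Only features of type `gene` are kept. The identifier is the `ID`
#' attribute (falling back to `locus_tag` when `ID` is absent). Coordinates
#' stay 1-based inclusive. Genes with strand "." are treated as `+` with a
#' warning.
#'
#' @param gff3_path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `contig_id`, `start`, `end`,
#'   `strand`.
#' @export
read_genes <- function(gff3_path) {
  gff <- rtracklayer::readGFF(gff3_path)
  gff <- as.data.frame(gff, stringsAsFactors = FALSE)
  is_gene <- gff$type == "gene"
  if (!any(is_gene)) {
    warning("no gene features found in ", gff3_path)
    return(data.frame(gene_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  g <- gff[is_gene, , drop = FALSE]
  ids <- if (is.null(g$ID)) rep(NA_character_, nrow(g)) else
    as.character(g$ID)
  if ("locus_tag" %in% names(g)) {
    lt <- as.character(g$locus_tag)
    ids[is.na(ids) | ids == ""] <- lt[is.na(ids) | ids == ""]
  }
  bad <- which(is.na(ids) | ids == "")
  if (length(bad)) {
    stop("gene feature(s) without ID attribute in ", gff3_path, ": ",
         paste(sprintf("%s:%d-%d", g$seqid[bad], g$start[bad], g$end[bad]),
               collapse = "; "))
  }
  if (any(g$start > g$end)) {
    i <- which(g$start > g$end)[1L]
    stop("gene ", ids[i], " has start > end (", g$start[i], " > ", g$end[i], ")")
  }
  strand <- as.character(g$strand)
  undec <- is.na(strand) | !(strand %in% c("+", "-"))
  if (any(undec)) {
    warning(sum(undec), " gene(s) without strand; treated as '+': ",
            paste(utils::head(ids[undec], 5L), collapse = ", "))
    strand[undec] <- "+"
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s) in ", gff3_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(gene_id = ids, contig_id = as.character(g$seqid),
             start = as.integer(g$start), end = as.integer(g$end),
             strand = strand, stringsAsFactors = FALSE, row.names = NULL)
}

#' Reverse-complement a DNA string
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Extract the upstream promoter of one gene
#'
#' For a `+` strand gene the promoter is the 0-based half-open genomic
#' interval `[start-1-length, start-1)`, clipped at the contig start; for a
#' `-` strand gene it is `[end, end+length)`, clipped at the contig end and
#' reverse-complemented so the returned sequence reads 5'->3' towards the
#' gene. `truncated` is TRUE iff clipping shortened the sequence.
#'
#' @param gene A single-row data.frame (or list) with `gene_id`, `contig_id`,
#'   `start`, `end`, `strand`.
#' @param genome Named character vector from [read_genome()].
#' @param length Requested promoter length in bp (default 1000).
#' @return A one-row data.frame: `gene_id`, `contig_id`, `int_start`,
#'   `int_end` (0-based half-open), `strand`, `sequence`, `truncated`.
#' @export
extract_promoter <- function(gene, genome, length = 1000L) {
  stopifnot(length >= 1L)
  contig <- as.character(gene$contig_id)
  if (!contig %in% names(genome)) {
    stop("contig '", contig, "' for gene '", gene$gene_id,
         "' not present in genome")
  }
  clen <- nchar(genome[[contig]])
  if (gene$strand == "+") {
    int_end <- gene$start - 1L                 # 0-based half-open
    int_start <- max(0L, int_end - as.integer(length))
  } else {
    int_start <- gene$end                      # 0-based == 1-based end
    int_end <- min(clen, int_start + as.integer(length))
  }
  if (int_end > int_start) {
    seq <- substr(genome[[contig]], int_start + 1L, int_end)
    if (gene$strand == "-") seq <- revcomp(seq)
  } else {
    int_end <- int_start
    seq <- ""
  }
  data.frame(gene_id = as.character(gene$gene_id), contig_id = contig,
             int_start = int_start, int_end = int_end,
             strand = as.character(gene$strand), sequence = unname(seq),
             truncated = (int_end - int_start) < length,
             stringsAsFactors = FALSE)
}

#' Extract promoters for a table of genes
#'
#' @param genes data.frame from [read_genes()].
#' @param genome Named character vector from [read_genome()].
#' @param length Promoter length in bp.
#' @return data.frame with one PromoterRecord row per gene.
#' @export
extract_promoters <- function(genes, genome, length = 1000L) {
  out <- lapply(seq_len(nrow(genes)), function(i) {
    extract_promoter(genes[i, , drop = FALSE], genome, length)
  })
  do.call(rbind, out)
}

#' Write promoter records to FASTA
#'
#' Headers have the form `gene_id contig:int_start-int_end(strand)`; the file
#' round-trips through [read_genome()] (ids are the first header token).
#' Records with empty sequences are written with a zero-length body and a
#' warning.
#'
#' @param records data.frame of PromoterRecords.
#' @param fasta_path Output path.
#' @return Invisibly, `fasta_path`.
#' @export
write_promoters <- function(records, fasta_path) {
  stopifnot(nrow(records) > 0L)
  if (any(records$sequence == "")) {
    warning(sum(records$sequence == ""),
            " promoter record(s) have empty sequences")
  }
  headers <- sprintf("%s %s:%d-%d(%s)", records$gene_id, records$contig_id,
                     records$int_start, records$int_end, records$strand)
  lines <- character(0L)
  for (i in seq_len(nrow(records))) {
    body <- records$sequence[i]
    lines <- c(lines, paste0(">", headers[i]),
               if (nzchar(body)) gsub("(.{70})", "\\1\n", body) else "")
  }
  writeLines(lines, fasta_path)
  invisible(fasta_path)
}
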