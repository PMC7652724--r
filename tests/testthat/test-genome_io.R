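write_fasta <- function(recs, path) {
  writeLines(unlist(lapply(names(recs), function(n) {
    c(paste0(">", n), recs[[n]])
  })), path)
  path
}

test_that("read_genome parses, upper-cases and keeps ambiguity codes", {
  fa <- write_fasta(list("ctg1 some description" = "acgtACGT",
                         "ctg2" = "ANNNT"), withr::local_tempfile())
  g <- read_genome(fa)
  expect_named(g, c("ctg1", "ctg2"))
  expect_identical(unname(g["ctg1"]), "ACGTACGT")
  expect_identical(unname(g["ctg2"]), "ANNNT")
})

test_that("read_genome rejects duplicate contig ids and empty files", {
  fa <- write_fasta(list("c1" = "ACGT", "c1 other" = "TTTT"),
                    withr::local_tempfile())
  expect_error(read_genome(fa), "duplicate contig")
  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_error(read_genome(empty))
})

gff_lines <- function(rows) {
  c("##gff-version 3", rows)
}

test_that("read_genes keeps gene features with 1-based coordinates", {
  gff <- withr::local_tempfile()
  writeLines(gff_lines(c(
    "ctg1\tsrc\tgene\t101\t400\t.\t-\t.\tID=g2",
    "ctg1\tsrc\tmRNA\t101\t400\t.\t-\t.\tID=g2.t1;Parent=g2",
    "ctg1\tsrc\tgene\t500\t900\t.\t+\t.\tID=g1",
    "ctg2\tsrc\tgene\t10\t50\t.\t+\t.\tID=g3")), gff)
  genes <- read_genes(gff)
  expect_equal(nrow(genes), 3L)
  g2 <- genes[genes$gene_id == "g2", ]
  expect_equal(g2$contig_id, "ctg1")
  expect_equal(g2$start, 101L)
  expect_equal(g2$end, 400L)
  expect_equal(g2$strand, "-")
})

test_that("read_genes warns on gene-less files and '.' strands, errors on bad rows", {
  gff <- withr::local_tempfile()
  writeLines(gff_lines("ctg1\tsrc\tmRNA\t1\t10\t.\t+\t.\tID=t1"), gff)
  expect_warning(genes <- read_genes(gff), "no gene features")
  expect_equal(nrow(genes), 0L)

  gff2 <- withr::local_tempfile()
  writeLines(gff_lines("ctg1\tsrc\tgene\t5\t20\t.\t.\t.\tID=g1"), gff2)
  expect_warning(g <- read_genes(gff2), "without strand")
  expect_equal(g$strand, "+")

  gff3 <- withr::local_tempfile()
  writeLines(gff_lines("ctg1\tsrc\tgene\t30\t20\t.\t+\t.\tID=g1"), gff3)
  expect_error(read_genes(gff3), "start > end")

  gff4 <- withr::local_tempfile()
  writeLines(gff_lines("ctg1\tsrc\tgene\t1\t20\t.\t+\t.\tNote=x"), gff4)
  expect_error(read_genes(gff4), "without ID")
})

test_that("promoter extraction follows the stated interval conventions", {
  genome <- c(ctgA = paste(rep("ACGT", 2500), collapse = ""))  # 10 kb
  gene <- data.frame(gene_id = "gp", contig_id = "ctgA", start = 5001L,
                     end = 5300L, strand = "+", stringsAsFactors = FALSE)
  p <- extract_promoter(gene, genome, 1000L)
  expect_equal(p$int_start, 4000L)
  expect_equal(p$int_end, 5000L)
  expect_equal(nchar(p$sequence), 1000L)
  expect_false(p$truncated)
  expect_identical(p$sequence, substr(genome[["ctgA"]], 4001, 5000))

  # gene starting at the contig edge: empty promoter, truncated
  g2 <- data.frame(gene_id = "ge", contig_id = "ctgA", start = 1L,
                   end = 300L, strand = "+", stringsAsFactors = FALSE)
  p2 <- extract_promoter(g2, genome, 1000L)
  expect_identical(p2$sequence, "")
  expect_true(p2$truncated)

  # minus-strand promoter is the reverse complement of the downstream slice
  genomeA <- c(A = strrep("A", 2000))
  g3 <- data.frame(gene_id = "gm", contig_id = "A", start = 100L,
                   end = 300L, strand = "-", stringsAsFactors = FALSE)
  p3 <- extract_promoter(g3, genomeA, 1000L)
  expect_identical(p3$sequence, strrep("T", 1000))
  expect_equal(p3$int_start, 300L)
  expect_equal(p3$int_end, 1300L)

  expect_error(extract_promoter(
    data.frame(gene_id = "gx", contig_id = "nope", start = 1L, end = 2L,
               strand = "+"), genome), "nope")
})

test_that("promoter length + clipped bases is the requested length", {
  set.seed(42)
  genome <- c(c1 = rand_dna_test(3000))
  for (i in 1:20) {
    start <- sample(3000L, 1L)
    end <- min(3000L, start + 99L)
    strand <- sample(c("+", "-"), 1L)
    g <- data.frame(gene_id = "g", contig_id = "c1", start = start,
                    end = end, strand = strand)
    p <- extract_promoter(g, genome, 500L)
    clipped <- if (strand == "+") max(0L, 500L - (start - 1L)) else
      max(0L, 500L - (3000L - end))
    expect_equal(nchar(p$sequence) + clipped, 500L)
    expect_equal(p$truncated, clipped > 0L)
    # promoter interval never overlaps the gene's own span
    expect_true(p$int_end <= start - 1L || p$int_start >= end)
  }
})

test_that("extraction is invariant under reverse-complementing the contig", {
  set.seed(7)
  seq <- rand_dna_test(2000)
  genome <- c(c1 = seq)
  genome_rc <- c(c1 = revcomp(seq))
  g <- data.frame(gene_id = "g", contig_id = "c1", start = 1200L,
                  end = 1400L, strand = "+")
  g_flip <- data.frame(gene_id = "g", contig_id = "c1",
                       start = 2000L - 1400L + 1L, end = 2000L - 1200L + 1L,
                       strand = "-")
  p1 <- extract_promoter(g, genome, 300L)
  p2 <- extract_promoter(g_flip, genome_rc, 300L)
  expect_identical(p1$sequence, p2$sequence)
})

test_that("write_promoters round-trips through read_genome", {
  genome <- c(c1 = strrep("ACGTT", 400))
  genes <- data.frame(gene_id = c("a", "b"), contig_id = "c1",
                      start = c(900L, 1500L), end = c(1000L, 1600L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  pr <- extract_promoters(genes, genome, 200L)
  fa <- withr::local_tempfile()
  write_promoters(pr, fa)
  back <- read_genome(fa)
  expect_named(back, c("a", "b"))
  expect_identical(unname(back), pr$sequence)

  pr2 <- pr
  pr2$sequence[1] <- ""
  expect_warning(write_promoters(pr2, fa), "empty")
})
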