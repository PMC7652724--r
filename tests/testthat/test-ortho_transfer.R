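write_ortho <- function(rows, path,
                        species = c("Anidulans", "Ncrassa", "Target")) {
  writeLines(c(paste(c("# Species", "Genes", "Alg.-Conn.", species),
                     collapse = "\t"), rows), path)
  path
}

test_that("ProteinOrtho rows expand to per-protein pairs with '*' absence", {
  p <- write_ortho(c(
    "3\t3\t1\tAn_g1\tNc_g1\tT_g1",
    "2\t2\t1\tAn_g2\tNc_g2\t*",
    "3\t4\t1\tAn_g3a,An_g3b\tNc_g3\tT_g3",
    "2\t3\t1\tAn_g4\t*\tT_g4a,T_g4b"), withr::local_tempfile())
  pairs <- read_proteinortho(p, "Target", c("Anidulans", "Ncrassa"))
  # row 2 contributes nothing (no target ortholog)
  expect_false(any(pairs$source_protein %in% c("An_g2", "Nc_g2")))
  # row 3: 2 An co-orthologs + 1 Nc, one target -> 3 pairs, same group
  r3 <- pairs[pairs$group_id == 3L, ]
  expect_equal(nrow(r3), 3L)
  expect_setequal(r3$source_protein, c("An_g3a", "An_g3b", "Nc_g3"))
  # row 4: An fans out to both target co-orthologs
  r4 <- pairs[pairs$group_id == 4L, ]
  expect_equal(nrow(r4), 2L)
  expect_setequal(r4$target_protein, c("T_g4a", "T_g4b"))
  # total = hand-computed sum of per-row cross products
  expect_equal(nrow(pairs), 2L + 3L + 2L)
  expect_error(read_proteinortho(p, "Missing", "Anidulans"), "Missing")
})

test_that("interaction tables normalize effects, dedupe, and cross-validate", {
  p <- withr::local_tempfile()
  writeLines(c("tf_id\ttg_id\teffect",
               "tfA\tg1\tPositive", "tfA\tg2\tnegative",
               "tfA\tg2\tnegative", "tfA\tg3\t", "tfB\tgX\tpositive"), p)
  expect_warning(
    ints <- read_interactions(p, "Anidulans",
                              gene_list = c("tfA", "tfB", "g1", "g2", "g3")),
    "discarded")
  expect_equal(nrow(ints), 3L)  # dedup + gX dropped
  expect_equal(ints$effect[ints$tg_id == "g1"], "positive")
  expect_equal(ints$effect[ints$tg_id == "g3"], "unknown")

  ints2 <- read_interactions(p, "Anidulans")  # no gene list: keep all
  expect_equal(nrow(ints2), 4L)
})

test_that("transfer requires orthologs on both sides and expands cross-products", {
  pairs <- data.frame(
    source_species = c("Anidulans", "Anidulans", "Anidulans"),
    source_protein = c("An_tf", "An_tf", "An_tg"),
    target_protein = c("T_tf1", "T_tf2", "T_tg"),
    group_id = c(1L, 1L, 2L), stringsAsFactors = FALSE)
  ints <- data.frame(source_species = "Anidulans", tf_id = "An_tf",
                     tg_id = "An_tg", effect = "positive",
                     stringsAsFactors = FALSE)
  edges <- transfer_interactions(ints, pairs)
  expect_equal(nrow(edges), 2L)  # 2 TF co-orthologs x 1 TG ortholog
  expect_setequal(edges$tf_id, c("T_tf1", "T_tf2"))

  # TG without ortholog -> nothing
  ints2 <- data.frame(source_species = "Anidulans", tf_id = "An_tf",
                      tg_id = "An_orphan", effect = "positive",
                      stringsAsFactors = FALSE)
  expect_equal(nrow(transfer_interactions(ints2, pairs)), 0L)
  expect_equal(nrow(transfer_interactions(ints[0, ], pairs)), 0L)
})

test_that("transfer is monotone in the ortholog table", {
  set.seed(3)
  ints <- data.frame(source_species = "Anidulans",
                     tf_id = sprintf("An_tf%d", sample(3, 10, TRUE)),
                     tg_id = sprintf("An_tg%d", sample(6, 10, TRUE)),
                     effect = "unknown", stringsAsFactors = FALSE)
  base_pairs <- data.frame(
    source_species = "Anidulans",
    source_protein = c("An_tf1", "An_tg1", "An_tg2"),
    target_protein = c("T_tf1", "T_tg1", "T_tg2"),
    group_id = 1:3, stringsAsFactors = FALSE)
  more_pairs <- rbind(base_pairs, data.frame(
    source_species = "Anidulans", source_protein = c("An_tf2", "An_tg3"),
    target_protein = c("T_tf2", "T_tg3"), group_id = 4:5,
    stringsAsFactors = FALSE))
  e1 <- transfer_interactions(ints, base_pairs)
  e2 <- transfer_interactions(ints, more_pairs)
  k <- function(d) paste(d$tf_id, d$tg_id, d$source_species)
  expect_true(all(k(e1) %in% k(e2)))
})

test_that("provenance merge unions species, resolves signs, sums weights", {
  edges <- data.frame(
    tf_id = c("T_tf", "T_tf", "T_tf", "T_tf"),
    tg_id = c("T_g1", "T_g1", "T_g2", "T_g3"),
    source_species = c("Anidulans", "Ncrassa", "Anidulans", "Anidulans"),
    effect = c("positive", "positive", "positive", "unknown"),
    stringsAsFactors = FALSE)
  edges <- rbind(edges, data.frame(
    tf_id = "T_tf", tg_id = "T_g2", source_species = "Ncrassa",
    effect = "negative", stringsAsFactors = FALSE))
  m <- merge_provenance(edges,
                        species_order = c("Anidulans", "Ncrassa"))
  g1 <- m[m$tg_id == "T_g1", ]
  expect_equal(g1$provenance, "Anidulans;Ncrassa")
  expect_equal(g1$effect, "positive")
  expect_equal(g1$weight, 2)
  expect_equal(g1$n_sources, 2L)
  # sign conflict -> unknown
  expect_equal(m$effect[m$tg_id == "T_g2"], "unknown")
  # single source -> weight 1, singleton provenance
  g3 <- m[m$tg_id == "T_g3", ]
  expect_equal(g3$weight, 1)
  expect_equal(g3$provenance, "Anidulans")
  # a sign beats unknown
  e2 <- data.frame(tf_id = "a", tg_id = "b",
                   source_species = c("Anidulans", "Ncrassa"),
                   effect = c("unknown", "negative"),
                   stringsAsFactors = FALSE)
  expect_equal(merge_provenance(e2)$effect, "negative")
  # custom weights; unknown species rejected
  m2 <- merge_provenance(edges, weight_scheme = c(Anidulans = 2, Ncrassa = 0.5))
  expect_equal(m2$weight[m2$tg_id == "T_g1"], 2.5)
  expect_error(merge_provenance(edges, weight_scheme = c(Anidulans = 1)),
               "without a weight")
})

test_that("provenance-category counts partition the merged edge set", {
  for (seed in 1:3) {
    fx <- generate_fixture(fixture_config(seed = seed),
                           withr::local_tempdir())
    cnt <- table(fx$truth$edges$n_sources)
    expect_equal(sum(cnt), nrow(fx$truth$edges))
  }
})
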