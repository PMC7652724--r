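write_cisbp <- function(probs, path) {
  lines <- c("Pos\tA\tC\tG\tT",
             vapply(seq_len(nrow(probs)), function(i) {
               paste(c(i, probs[i, ]), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  path
}

test_that("CIS-BP parsing accepts frequencies and rejects other dialects", {
  p <- write_cisbp(matrix(c(0.25, 0.25, 0.25, 0.25,
                            0.97, 0.01, 0.01, 0.01,
                            0.1, 0.2, 0.3, 0.4),
                          nrow = 3, byrow = TRUE), withr::local_tempfile())
  m <- read_cisbp_matrix(p, matrix_id = "M1")
  expect_equal(m$width, 3L)
  expect_equal(unname(m$probs[1, ]), rep(0.25, 4))
  expect_equal(rowSums(m$probs), rep(1, 3), tolerance = 1e-12)

  counts <- write_cisbp(matrix(c(1, 8, 0, 0), nrow = 1),
                        withr::local_tempfile())
  expect_error(read_cisbp_matrix(counts), "counts dialect")

  bad <- withr::local_tempfile()
  writeLines(c("Pos\tA\tC\tG\tT", "1\t0.5\tx\t0.25\t0.25"), bad)
  expect_error(read_cisbp_matrix(bad), "non-numeric")
})

test_that("log-odds scores follow the stated formula", {
  freq <- structure(list(matrix_id = "M", tf_id = NA_character_, width = 2L,
                         probs = matrix(c(0.25, 0.25, 0.25, 0.25,
                                          1, 0, 0, 0), nrow = 2,
                                        byrow = TRUE,
                                        dimnames = list(NULL, c("A", "C", "G", "T")))),
                    class = "FrequencyMatrix")
  bg <- uniform_background()
  lom <- to_log_odds(freq, bg, pseudocount = 0.01)
  # uniform position against uniform background scores 0 everywhere
  expect_equal(unname(lom$scores[1, ]), rep(0, 4), tolerance = 1e-12)
  # certain position: score(A) = log2((1 + 0.01*0.25) / (1.01*0.25))
  expect_equal(unname(lom$scores[2, "A"]),
               log2((1 + 0.01 * 0.25) / (1.01 * 0.25)), tolerance = 1e-12)
  # with pseudocount -> 0 that score approaches exactly 2 bits
  lom0 <- to_log_odds(structure(list(matrix_id = "M", tf_id = NA, width = 1L,
                                     probs = matrix(c(0.7, 0.1, 0.1, 0.1), 1,
                                                    dimnames = list(NULL, c("A", "C", "G", "T")))),
                                class = "FrequencyMatrix"), bg, 0)
  expect_equal(unname(lom0$scores[1, "A"]), log2(0.7 / 0.25),
               tolerance = 1e-12)
  # doubling the pseudocount shrinks every |score| toward 0
  l1 <- to_log_odds(freq, bg, 0.01)$scores
  l2 <- to_log_odds(freq, bg, 0.02)$scores
  expect_true(all(abs(l2) <= abs(l1) + 1e-12))
  expect_error(to_log_odds(freq, c(A = 0, C = 0.5, G = 0.25, T = 0.25)),
               "positive")
})

test_that("exact DP survival equals brute-force enumeration (w <= 6)", {
  set.seed(101)
  for (w in c(1L, 3L, 4L, 6L)) {
    for (rep in 1:2) {
      freq <- random_freq(w)
      bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
      if (rep == 2) bg <- uniform_background()
      lom <- to_log_odds(freq, bg)
      dist <- score_distribution(lom, bg, granularity = 0.001)
      oracle <- brute_survival_fn(dist$score_ints, bg)
      expect_equal(sum(dist$pmf), 1, tolerance = 1e-9)
      ints_grid <- dist$min_int + seq_along(dist$pmf) - 1L
      got <- dist$survival
      want <- vapply(ints_grid, oracle, 1)
      expect_equal(got, want, tolerance = 1e-12)
      # survival is non-increasing and 1 at the minimum score
      expect_true(all(diff(got) <= 1e-15))
      expect_equal(got[1], 1, tolerance = 1e-12)
    }
  }
})

test_that("degenerate distributions behave as closed forms predict", {
  bg <- uniform_background()
  # width-1 all-A matrix: survival at score(A) is bg(A) = 0.25
  freq <- structure(list(matrix_id = "M", tf_id = NA, width = 1L,
                         probs = matrix(c(1, 0, 0, 0), 1,
                                        dimnames = list(NULL, c("A", "C", "G", "T")))),
                    class = "FrequencyMatrix")
  lom <- to_log_odds(freq, bg, 0.01)
  d <- score_distribution(lom, bg)
  a_int <- d$score_ints[1, "A"]
  expect_equal(survival_at_test(d, a_int), 0.25, tolerance = 1e-12)
  # uniform matrix: every word scores 0, survival(0) = 1
  fu <- structure(list(matrix_id = "M", tf_id = NA, width = 4L,
                       probs = matrix(0.25, 4, 4,
                                      dimnames = list(NULL, c("A", "C", "G", "T")))),
                  class = "FrequencyMatrix")
  du <- score_distribution(to_log_odds(fu, bg), bg)
  expect_equal(length(du$pmf), 1L)
  expect_equal(survival_at_test(du, 0L), 1)
  # support cap triggers a helpful error
  expect_error(score_distribution(lom, bg, granularity = 1e-9,
                                  max_support = 1000),
               "coarser granularity")
})

test_that("scanning finds planted sites, respects strand symmetry and threshold", {
  set.seed(5)
  w <- 9L
  consensus <- strsplit(rand_dna_test(w), "")[[1]]
  probs <- matrix(0.01, w, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(w)) probs[i, consensus[i]] <- 0.97
  freq <- structure(list(matrix_id = "Mx", tf_id = "tf1", width = w,
                         probs = probs), class = "FrequencyMatrix")
  bg <- uniform_background()
  lom <- to_log_odds(freq, bg)
  dist <- score_distribution(lom, bg)

  seq <- rand_dna_test(400)
  offset <- 150L
  substr(seq, offset + 1L, offset + w) <- paste(consensus, collapse = "")
  hits <- scan_promoter(list(gene_id = "g", sequence = seq), lom, dist)
  plus <- hits[hits$strand == "+", ]
  expect_true(any(plus$offset == offset))
  expect_true(all(hits$p_value <= 1e-4))
  # every reported + strand word matches the promoter slice
  for (i in which(hits$strand == "+")) {
    expect_identical(hits$word[i],
                     substr(seq, hits$offset[i] + 1, hits$offset[i] + w))
  }
  # strand symmetry: scanning the reverse complement mirrors offsets/strands
  hits_rc <- scan_promoter(list(gene_id = "g", sequence = revcomp(seq)),
                           lom, dist)
  L <- nchar(seq)
  mirrored <- data.frame(offset = L - w - hits_rc$offset,
                         strand = ifelse(hits_rc$strand == "+", "-", "+"),
                         score = hits_rc$score)
  o <- order(mirrored$offset, mirrored$strand)
  expect_equal(mirrored$offset[o], hits$offset)
  expect_equal(mirrored$strand[o], hits$strand)
  expect_equal(mirrored$score[o], hits$score)

  # lowering the threshold never adds hits
  hits_lo <- scan_promoter(list(gene_id = "g", sequence = seq), lom, dist,
                           p_threshold = 1e-8)
  expect_true(nrow(hits_lo) <= nrow(hits))
  k <- paste(hits$offset, hits$strand)
  expect_true(all(paste(hits_lo$offset, hits_lo$strand) %in% k))

  # short promoter and non-ACGT windows
  expect_equal(nrow(scan_promoter(list(gene_id = "g", sequence = "ACG"),
                                  lom, dist)), 0L)
  seqN <- seq
  substr(seqN, offset + 3L, offset + 3L) <- "N"
  hitsN <- scan_promoter(list(gene_id = "g", sequence = seqN), lom, dist)
  expect_false(any(hitsN$offset == offset & hitsN$strand == "+"))
})

test_that("scan agrees with a brute-force window oracle on a small case", {
  set.seed(9)
  freq <- random_freq(4L)
  bg <- c(A = 0.2, C = 0.3, G = 0.3, T = 0.2)
  lom <- to_log_odds(freq, bg)
  dist <- score_distribution(lom, bg)
  seq <- rand_dna_test(60)
  thr <- 0.05  # loose threshold so the oracle sees plenty of hits
  hits <- scan_promoter(list(gene_id = "g", sequence = seq), lom, dist,
                        p_threshold = thr)
  oracle <- brute_survival_fn(dist$score_ints, bg)
  codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  rc_codes <- rev(5L - codes)
  expected <- list()
  for (str in c("+", "-")) {
    cc <- if (str == "+") codes else rc_codes
    for (s in 1:(length(cc) - 3L)) {
      sc <- sum(dist$score_ints[cbind(1:4, cc[s:(s + 3L)])])
      if (oracle(sc) <= thr) {
        off <- if (str == "+") s - 1L else length(cc) - 4L + 1L - s
        expected[[length(expected) + 1L]] <- paste(off, str)
      }
    }
  }
  expect_setequal(paste(hits$offset, hits$strand), unlist(expected))
})

test_that("per-edge TFBS counting joins hits and flags missing matrices", {
  edges <- data.frame(tf_id = c("tf1", "tf1", "tf2"),
                      tg_id = c("g1", "g2", "g1"),
                      provenance = "Anidulans", n_sources = 1L,
                      effect = "unknown", weight = 1,
                      tfbs_count = NA_integer_, stringsAsFactors = FALSE)
  hits <- data.frame(gene_id = c("g1", "g1", "g1"),
                     matrix_id = c("M1", "M1", "M1"),
                     tf_id = "tf1",
                     offset = c(10L, 10L, 50L), strand = "+",
                     word = "AAAA", score = 5, p_value = 1e-5,
                     stringsAsFactors = FALSE)
  out <- count_hits_per_edge(edges, hits, c(M1 = "tf1"))
  # duplicate hit row deduplicated: 2 distinct sites on (tf1, g1)
  expect_equal(out$tfbs_count, c(2L, 0L, 0L))
  expect_equal(out$no_matrix, c(FALSE, FALSE, TRUE))
})

test_that("background model estimation is a proper distribution", {
  bg <- estimate_background(c("AAAACC", "GGTTNN"))
  expect_equal(sum(bg), 1, tolerance = 1e-12)
  expect_true(all(bg > 0))
  expect_true(bg["A"] > bg["C"])
})
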