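# Independent brute-force oracles and small builders used across tests.
# These deliberately avoid the package's own DP / igraph code paths.

# Enumerate all 4^w words: exact survival of the lattice window score.
# Returns a function p(score_int) = P(score_int(word) >= s).
brute_survival_fn <- function(score_ints, bg) {
  w <- nrow(score_ints)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  tot <- integer(nrow(words))
  prob <- rep(1, nrow(words))
  for (i in seq_len(w)) {
    tot <- tot + score_ints[i, words[, i]]
    prob <- prob * bg[words[, i]]
  }
  function(s) sum(prob[tot >= s])
}

# Directed betweenness: Floyd-Warshall distances, then shortest-path counts
# by dynamic programming over increasing distance.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  ds <- sort(unique(d[is.finite(d) & d > 0]))
  for (dist_k in ds) {
    for (i in 1:n) for (j in 1:n) {
      if (i != j && d[i, j] == dist_k) {
        if (dist_k == 1) sigma[i, j] <- 1
        else {
          preds <- which(adj[, j] == 1 & d[i, ] == dist_k - 1)
          sigma[i, j] <- sum(sigma[i, preds])
        }
      }
    }
  }
  bet <- numeric(n)
  for (v in 1:n) {
    acc <- 0
    for (s in 1:n) for (t in 1:n) {
      if (s == t || s == v || t == v) next
      if (!is.finite(d[s, t])) next
      if (d[s, v] + d[v, t] == d[s, t]) {
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    bet[v] <- acc
  }
  bet
}

# Local clustering coefficients by triangle counting on the undirected
# simple projection (loops removed).
brute_clustering <- function(adj) {
  n <- nrow(adj)
  u <- (adj + t(adj)) > 0
  diag(u) <- FALSE
  vapply(1:n, function(v) {
    nb <- which(u[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && u[nb[a], nb[b]]) tri <- tri + 1
    }
    2 * tri / (k * (k - 1))
  }, 1)
}

survival_at_test <- function(dist, score_int) {
  funregnet:::survival_at(dist, score_int)
}

rand_dna_test <- function(n, bg = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(bg), n, replace = TRUE, prob = bg), collapse = "")
}

# Build a grn object from parallel tf/tg id vectors (unit weights).
toy_network <- function(tf, tg) {
  e <- data.frame(tf_id = tf, tg_id = tg, provenance = "Anidulans",
                  n_sources = 1L, effect = "unknown", weight = 1,
                  tfbs_count = NA_integer_, stringsAsFactors = FALSE)
  build_network(e)
}

# grn from an adjacency matrix with node names "n1".."nN".
adj_network <- function(adj) {
  idx <- which(adj == 1, arr.ind = TRUE)
  nm <- paste0("n", 1:nrow(adj))
  e <- data.frame(tf_id = nm[idx[, 1]], tg_id = nm[idx[, 2]],
                  provenance = "Anidulans", n_sources = 1L,
                  effect = "unknown", weight = 1,
                  tfbs_count = NA_integer_, stringsAsFactors = FALSE)
  net <- build_network(e)
  # keep isolated nodes too
  net$nodes <- data.frame(gene_id = nm, is_tf = nm %in% e$tf_id,
                          is_tg = nm %in% e$tg_id, stringsAsFactors = FALSE)
  net
}

# Random frequency matrix (rows on the simplex), seeded by caller.
random_freq <- function(w, matrix_id = "Mtest") {
  p <- matrix(stats::rgamma(4 * w, shape = 1), nrow = w)
  p <- p / rowSums(p)
  colnames(p) <- c("A", "C", "G", "T")
  structure(list(matrix_id = matrix_id, tf_id = NA_character_,
                 width = w, probs = p), class = "FrequencyMatrix")
}

# Generate a default fixture in a temp dir and run the whole pipeline on it.
run_fixture_pipeline <- function(seed = 1L, cfg = fixture_config(seed = seed),
                                 root = withr::local_tempdir(.local_envir =
                                                               parent.frame())) {
  fx <- generate_fixture(cfg, file.path(root, "fx"))
  pc <- pipeline_config(
    genome = fx$paths$genome, gff3 = fx$paths$gff3, ortho = fx$paths$ortho,
    interactions = stats::setNames(
      lapply(fx$species, function(sp) fx$paths[[paste0("interactions_", sp)]]),
      fx$species),
    matrix_dir = fx$paths$matrix_dir,
    matrix_tf_map = fx$paths$matrix_tf_map,
    terms = fx$paths$terms, out_dir = file.path(root, "run"),
    target_species = "Target")
  manifest <- run_pipeline(pc)
  list(fx = fx, config = pc, manifest = manifest,
       edges = utils::read.delim(file.path(root, "run", "edges.tsv"),
                                 stringsAsFactors = FALSE),
       hits = utils::read.delim(file.path(root, "run", "tfbs_hits.tsv"),
                                stringsAsFactors = FALSE),
       out_dir = file.path(root, "run"))
}
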