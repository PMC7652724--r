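# Position-weight-matrix scanning with exact per-site p-values.
#
# A CIS-BP frequency matrix is converted to a log2-odds matrix against a
# 0-order background; the null distribution of window scores is computed
# EXACTLY by dynamic programming over a discretized score lattice (step =
# `granularity` bits), so each window's p-value P(score >= s) is exact at the
# lattice resolution rather than asymptotic. Both promoter strands are
# scanned; windows with p <= 1e-4 (default) are reported as candidate
# binding sites.

DNA_BASES <- c("A", "C", "G", "T")

#' Read one CIS-BP frequency matrix
#'
#' CIS-BP text layout: a header line `Pos A C G T` followed by one row per
#' motif position with base probabilities. Rows whose sum is within 1e-3 of
#' 1 are re-normalized; anything else (e.g. a counts-dialect file) is
#' rejected.
#'
#' @param path Path to the matrix file.
#' @param matrix_id Matrix identifier; defaults to the file name without
#'   extension (e.g. `M02621_2.00`).
#' @param tf_id Optional TF gene id bound by this motif.
#' @return A `FrequencyMatrix`: list with `matrix_id`, `tf_id`, `width` and
#'   `probs` (width x 4 matrix, columns A,C,G,T, rows summing to 1).
#' @export
read_cisbp_matrix <- function(path, matrix_id = NULL, tf_id = NA_character_) {
  if (is.null(matrix_id)) {
    matrix_id <- sub("\\.(txt|tsv|pwm)$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^Pos\\b", lines)
  if (length(hdr) != 1L) stop("no 'Pos A C G T' header in ", path)
  body <- lines[-seq_len(hdr)]
  if (!length(body)) stop("matrix ", path, " has no position rows")
  cells <- strsplit(body, "[\t ]+")
  probs <- matrix(NA_real_, nrow = length(cells), ncol = 4L,
                  dimnames = list(NULL, DNA_BASES))
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]][2:5]))
    if (anyNA(v) || length(cells[[i]]) < 5L) {
      stop("non-numeric cell in row ", i, " of ", path)
    }
    s <- sum(v)
    if (abs(s - 1) > 1e-3) {
      stop("row ", i, " of ", path, " sums to ", format(s),
           "; expected base frequencies summing to 1 (counts dialect not",
           " supported)")
    }
    probs[i, ] <- v / s
  }
  structure(list(matrix_id = matrix_id, tf_id = tf_id,
                 width = nrow(probs), probs = probs),
            class = "FrequencyMatrix")
}

#' Read every CIS-BP matrix in a directory
#'
#' @param dir Directory of `.txt` matrix files.
#' @param matrix_tf_map Optional named character vector `matrix_id -> tf_id`.
#' @return Named list of `FrequencyMatrix` objects keyed by `matrix_id`.
#' @export
read_cisbp_dir <- function(dir, matrix_tf_map = NULL) {
  files <- sort(list.files(dir, pattern = "\\.(txt|tsv|pwm)$",
                           full.names = TRUE))
  mats <- lapply(files, read_cisbp_matrix)
  names(mats) <- vapply(mats, `[[`, "", "matrix_id")
  if (!is.null(matrix_tf_map)) {
    for (m in names(mats)) {
      if (m %in% names(matrix_tf_map)) mats[[m]]$tf_id <- matrix_tf_map[[m]]
    }
  }
  mats
}

#' Uniform 0-order background
#' @return Named numeric vector of base probabilities (all 0.25).
#' @export
uniform_background <- function() {
  stats::setNames(rep(0.25, 4L), DNA_BASES)
}

#' Estimate a 0-order background from sequences
#'
#' Counts A/C/G/T over all supplied sequences (other characters ignored)
#' with a +1 pseudocount per base so every probability is strictly positive.
#'
#' @param sequences Character vector of DNA sequences (e.g. all scanned
#'   promoters).
#' @return Named numeric vector of base probabilities summing to 1.
#' @export
estimate_background <- function(sequences) {
  ch <- strsplit(toupper(paste(sequences, collapse = "")), "")[[1L]]
  counts <- table(factor(ch, levels = DNA_BASES)) + 1
  p <- as.numeric(counts) / sum(counts)
  stats::setNames(p, DNA_BASES)
}

#' Convert a frequency matrix to a log2-odds matrix
#'
#' `score(b, i) = log2((p[i,b] + pseudocount * bg[b]) /
#' ((1 + pseudocount) * bg[b]))`. The background-proportional pseudocount
#' keeps scores finite for zero-probability cells.
#'
#' @param freq A `FrequencyMatrix`.
#' @param bg Background probabilities over A,C,G,T (strictly positive).
#' @param pseudocount Non-negative pseudocount fraction (default 0.01).
#' @return A `LogOddsMatrix`: list with `matrix_id`, `tf_id`, `width`,
#'   `scores` (width x 4, bits).
#' @export
to_log_odds <- function(freq, bg, pseudocount = 0.01) {
  stopifnot(pseudocount >= 0)
  if (any(bg <= 0)) stop("background probabilities must be strictly positive")
  bg <- bg[DNA_BASES] / sum(bg[DNA_BASES])
  scores <- log2(sweep(freq$probs, 2L, pseudocount * bg, `+`) /
                   rep((1 + pseudocount) * bg, each = freq$width))
  if (any(!is.finite(scores))) {
    stop("non-finite log-odds scores; use a positive pseudocount for ",
         "matrices with zero cells")
  }
  structure(list(matrix_id = freq$matrix_id, tf_id = freq$tf_id,
                 width = freq$width, scores = scores, bg = bg),
            class = "LogOddsMatrix")
}

#' Exact null distribution of window scores
#'
#' Dynamic program: starting from a point mass at score 0, each motif
#' position convolves the current distribution with the four-outcome
#' distribution `{score(b, i) with probability bg[b]}`; scores are held on an
#' integer lattice of step `granularity` bits, so the resulting pmf and
#' survival function are exact at that resolution. Window scores computed by
#' [scan_promoter()] use the same lattice, making p-value lookups exact.
#'
#' @param lom A `LogOddsMatrix`.
#' @param bg Background probabilities; defaults to the background stored in
#'   `lom`.
#' @param granularity Score discretization step in bits (default 0.001).
#' @param max_support Cap on lattice support size; exceeding it raises an
#'   error suggesting a coarser granularity.
#' @return A `ScoreDistribution`: list with `granularity`, `score_ints`
#'   (width x 4 integer lattice scores), `min_int`, `scores` (lattice score
#'   values, bits), `pmf`, `survival` (P(score >= s), non-increasing).
#' @export
score_distribution <- function(lom, bg = NULL, granularity = 0.001,
                               max_support = 5e6) {
  stopifnot(granularity > 0)
  if (is.null(bg)) bg <- lom$bg
  bg <- bg[DNA_BASES] / sum(bg[DNA_BASES])
  ints_d <- round(lom$scores / granularity)
  support <- sum(apply(ints_d, 1L, max) - apply(ints_d, 1L, min)) + 1
  if (support > max_support || max(abs(ints_d)) >= .Machine$integer.max) {
    stop("score lattice support (", format(support),
         ") exceeds max_support; use a coarser granularity")
  }
  ints <- matrix(as.integer(ints_d), nrow = lom$width,
                 dimnames = dimnames(lom$scores))
  v <- 1
  vmin <- 0L
  for (i in seq_len(lom$width)) {
    row <- ints[i, ]
    rmin <- min(row)
    newlen <- length(v) + max(row) - rmin
    nv <- numeric(newlen)
    for (b in seq_len(4L)) {
      sh <- row[b] - rmin
      idx <- (1L + sh):(length(v) + sh)
      nv[idx] <- nv[idx] + v * bg[b]
    }
    v <- nv
    vmin <- vmin + rmin
  }
  keep <- v > 0
  first <- which(keep)[1L]
  last <- max(which(keep))
  pmf <- v[first:last]
  min_int <- vmin + first - 1L
  surv <- rev(cumsum(rev(pmf)))
  structure(list(granularity = granularity, score_ints = ints,
                 min_int = as.integer(min_int),
                 scores = (min_int + seq_along(pmf) - 1L) * granularity,
                 pmf = pmf, survival = surv),
            class = "ScoreDistribution")
}

# P(score >= s) for lattice scores given as integers.
survival_at <- function(dist, score_int) {
  i <- score_int - dist$min_int + 1L
  n <- length(dist$survival)
  out <- numeric(length(i))
  out[i <= 0L] <- 1
  inside <- i >= 1L & i <= n
  out[inside] <- dist$survival[i[inside]]
  # above the maximum achievable score: probability 0 (cannot occur for
  # scores produced by the same lattice)
  out
}

# Integer-lattice window scores over a coded sequence; NA where the window
# contains a non-ACGT character.
window_scores_int <- function(codes, ints) {
  w <- nrow(ints)
  n <- length(codes) - w + 1L
  if (n < 1L) return(integer(0L))
  total <- rep(0L, n)
  bad <- rep(FALSE, n)
  for (i in seq_len(w)) {
    ci <- codes[i:(n + i - 1L)]
    bad <- bad | is.na(ci)
    sc <- ints[i, ]
    v <- sc[ci]
    v[is.na(v)] <- 0L
    total <- total + v
  }
  total[bad] <- NA_integer_
  total
}

code_dna <- function(seq) {
  match(strsplit(toupper(seq), "")[[1L]], DNA_BASES)
}

#' Scan one promoter with a PWM, reporting exact-p hits on both strands
#'
#' Every window on the forward and reverse-complement strand is scored on
#' the shared lattice of `dist`; a window is a hit iff its exact p-value
#' `P(score >= s)` is at most `p_threshold`. Windows containing non-ACGT
#' characters are skipped. Offsets are 0-based positions of the window start
#' within the promoter (promoter orientation); for `-` strand hits `word` is
#' the reverse complement of the promoter slice (i.e. the motif-oriented
#' word).
#'
#' @param promoter One PromoterRecord row (needs `gene_id`, `sequence`), or
#'   a character scalar (then `gene_id` is `"seq"`).
#' @param lom A `LogOddsMatrix`.
#' @param dist Matching `ScoreDistribution`.
#' @param p_threshold Per-site p-value threshold (default 1e-4).
#' @return data.frame `gene_id`, `matrix_id`, `tf_id`, `offset`, `strand`,
#'   `word`, `score`, `p_value`, sorted by offset then strand.
#' @export
scan_promoter <- function(promoter, lom, dist, p_threshold = 1e-4) {
  if (is.character(promoter)) {
    promoter <- list(gene_id = "seq", sequence = promoter)
  }
  seq <- toupper(promoter$sequence)
  w <- lom$width
  empty <- data.frame(gene_id = character(), matrix_id = character(),
                      tf_id = character(), offset = integer(),
                      strand = character(), word = character(),
                      score = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  L <- nchar(seq)
  if (L < w) return(empty)
  codes <- code_dna(seq)
  rc <- revcomp(seq)
  codes_rc <- code_dna(rc)
  hits <- list()
  for (str in c("+", "-")) {
    cc <- if (str == "+") codes else codes_rc
    s_int <- window_scores_int(cc, dist$score_ints)
    ok <- !is.na(s_int)
    p <- rep(NA_real_, length(s_int))
    p[ok] <- survival_at(dist, s_int[ok])
    sel <- which(ok & p <= p_threshold)
    if (!length(sel)) next
    # map reverse-strand window starts back to promoter coordinates
    off <- if (str == "+") sel - 1L else L - w + 1L - sel
    word <- substr(rep(if (str == "+") seq else rc, length(sel)),
                   sel, sel + w - 1L)
    hits[[str]] <- data.frame(gene_id = as.character(promoter$gene_id),
                              matrix_id = lom$matrix_id, tf_id = lom$tf_id,
                              offset = as.integer(off), strand = str,
                              word = word,
                              score = s_int[sel] * dist$granularity,
                              p_value = p[sel], stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a promoter set with a set of matrices
#'
#' @param promoters data.frame of PromoterRecords ([extract_promoters()]).
#' @param matrices Named list of `FrequencyMatrix` objects.
#' @param bg Background model; `NULL` estimates a 0-order background from
#'   the promoter set itself.
#' @param pseudocount,granularity,p_threshold See [to_log_odds()] and
#'   [score_distribution()].
#' @param pairs Optional data.frame (`gene_id`, `matrix_id`) restricting the
#'   scan to specific promoter/matrix pairs (e.g. the promoters of the
#'   targets of each TF); `NULL` scans all promoters with all matrices.
#' @return data.frame of hits (see [scan_promoter()]).
#' @export
scan_promoters <- function(promoters, matrices, bg = NULL,
                           pseudocount = 0.01, granularity = 0.001,
                           p_threshold = 1e-4, pairs = NULL) {
  stopifnot(length(matrices) >= 1L)
  if (is.null(bg)) bg <- estimate_background(promoters$sequence)
  prepped <- lapply(matrices, function(m) {
    lom <- to_log_odds(m, bg, pseudocount)
    list(lom = lom, dist = score_distribution(lom, bg, granularity))
  })
  res <- list()
  for (mid in names(prepped)) {
    rows <- if (is.null(pairs)) seq_len(nrow(promoters)) else {
      which(promoters$gene_id %in% pairs$gene_id[pairs$matrix_id == mid])
    }
    for (i in rows) {
      h <- scan_promoter(promoters[i, , drop = FALSE],
                         prepped[[mid]]$lom, prepped[[mid]]$dist,
                         p_threshold)
      if (nrow(h)) res[[length(res) + 1L]] <- h
    }
  }
  if (!length(res)) {
    return(scan_promoter("", prepped[[1L]]$lom, prepped[[1L]]$dist))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fill per-edge TFBS counts from a hit table
#'
#' Hits join to edges through the target gene's promoter (`gene_id` ==
#' `tg_id`) and the matrix -> TF map. Duplicate hit rows are removed before
#' counting. Binding-site evidence annotates edges but never filters them:
#' edges with zero hits are retained, and edges whose TF has no matrix get
#' `tfbs_count = 0` and `no_matrix = TRUE`.
#'
#' @param edges Merged edge table from [merge_provenance()].
#' @param hits Hit table from [scan_promoters()].
#' @param matrix_tf_map Named character vector `matrix_id -> tf_id`; `NULL`
#'   uses the `tf_id` column of `hits`.
#' @return `edges` with `tfbs_count` filled and a `no_matrix` flag.
#' @export
count_hits_per_edge <- function(edges, hits, matrix_tf_map = NULL) {
  if (is.null(matrix_tf_map)) {
    m <- unique(hits[, c("matrix_id", "tf_id")])
    matrix_tf_map <- stats::setNames(m$tf_id, m$matrix_id)
  }
  hits <- unique(hits[, c("gene_id", "matrix_id", "offset", "strand")])
  hits$tf_id <- unname(matrix_tf_map[hits$matrix_id])
  tfs_with_matrix <- unique(stats::na.omit(unname(matrix_tf_map)))
  key <- paste(hits$tf_id, hits$gene_id, sep = "\r")
  tab <- table(key)
  ekey <- paste(edges$tf_id, edges$tg_id, sep = "\r")
  cnt <- as.integer(tab[ekey])
  cnt[is.na(cnt)] <- 0L
  edges$tfbs_count <- cnt
  edges$no_matrix <- !(edges$tf_id %in% tfs_with_matrix)
  edges
}
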