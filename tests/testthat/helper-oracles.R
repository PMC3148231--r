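# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package.

# Average-linkage (UPGMA) cophenetic distances via naive set merging.
oracle_upgma_cophenetic <- function(m) {
  n <- nrow(m)
  labels <- rownames(m)
  d <- as.matrix(dist(m, method = "euclidean"))
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      dij <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
      if (dij < best_d - 1e-12) { best_d <- dij; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Two-sided permutation p-value for a difference in means.
oracle_permutation_p <- function(x, y, n_perm = 2000) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  nx <- length(x)
  hits <- 0
  for (b in seq_len(n_perm)) {
    idx <- sample(length(pool), nx)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-15) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# Venn region count for one membership pattern via plain set algebra.
oracle_venn_region <- function(sets, pattern) {
  inside <- sets[pattern]
  outside <- sets[!pattern]
  region <- Reduce(intersect, inside)
  for (s in outside) region <- setdiff(region, s)
  length(region)
}

# Vote counting by nested loops.
oracle_vote_counts <- function(predictions) {
  pairs <- unique(paste(predictions$mirna_id, predictions$gene_id, sep = "\r"))
  vapply(pairs, function(p) {
    parts <- strsplit(p, "\r", fixed = TRUE)[[1]]
    sel <- predictions$mirna_id == parts[1] & predictions$gene_id == parts[2]
    length(unique(predictions$database[sel]))
  }, integer(1))
}

# A tiny deterministic rat+human study with no noise, used by several files.
noiseless_config <- function(seed = 1, ...) {
  generator_config(noise_sd = 0, scale_sd = 0, dropout_rate = 0, seed = seed, ...)
}
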