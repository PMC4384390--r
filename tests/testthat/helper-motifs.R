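# fixture builders and independent brute-force oracles

# motif with pure columns spelling a consensus string
pure_motif <- function(id, consensus) {
  letters <- strsplit(consensus, "")[[1]]
  mat <- t(vapply(letters, function(b) {
    v <- numeric(4); v[match(b, c("A", "C", "G", "T"))] <- 1; v
  }, numeric(4)))
  motif(id, mat)
}

# random row-stochastic motif (gamma-normalised rows)
rand_motif <- function(id, l, alpha = 1) {
  mat <- t(vapply(seq_len(l), function(i) {
    g <- rgamma(4, alpha); g / sum(g)
  }, numeric(4)))
  motif(id, mat)
}

# brute-force KFV: explicit loop over all 4^k words and all windows
bf_kfv <- function(m, k = 4, strand_policy = "both") {
  words <- kmer_names(k)
  count_one <- function(mat) {
    l <- nrow(mat)
    vapply(words, function(w) {
      codes <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
      tot <- 0
      for (i in seq_len(l - k + 1)) {
        p <- 1
        for (j in seq_len(k)) p <- p * mat[i + j - 1, codes[j]]
        tot <- tot + p
      }
      tot
    }, numeric(1))
  }
  v <- count_one(m$matrix)
  if (strand_policy == "both")
    v <- v + count_one(reverse_complement(m)$matrix)
  v
}

# brute-force nearest-medoid assignment (ties -> lowest medoid index)
bf_assign <- function(D, medoids) {
  medoids <- sort(medoids)
  vapply(seq_len(nrow(D)), function(i)
    medoids[which.min(D[i, medoids])], integer(1))
}

# brute-force silhouette: literal double loop over points and clusters
bf_silhouette <- function(D, labels) {
  n <- nrow(D)
  cls <- unique(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- Inf
    for (c in setdiff(cls, labels[i])) {
      mem <- which(labels == c)
      b <- min(b, mean(D[i, mem]))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

# exhaustive search over every (K, medoid set): the global optimum of the
# mean-silhouette objective over medoid-induced partitions
bf_best_fitness <- function(D) {
  n <- nrow(D)
  best <- -Inf
  for (K in 2:(n - 1)) {
    sets <- utils::combn(n, K)
    for (j in seq_len(ncol(sets))) {
      labels <- bf_assign(D, sets[, j])
      f <- mean(bf_silhouette(D, labels))
      if (f > best) best <- f
    }
  }
  best
}

# random symmetric distance matrix with zero diagonal, entries in [0, 1]
rand_dist <- function(n) {
  D <- matrix(runif(n * n), n)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(paste0("m", seq_len(n)), paste0("m", seq_len(n)))
  D
}

# distance matrix over random motifs (realistic cosine geometry)
rand_motif_dist <- function(n, l = 8) {
  motifs <- lapply(seq_len(n), function(i) rand_motif(paste0("m", i), l))
  build_distance_matrix(motifs, ic_threshold = 0)
}
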