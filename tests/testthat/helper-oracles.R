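# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (no shared tokenizer, no shared count tables).

# Naive sliding-window k-mer counter: character ops only.
brute_kmer_counts <- function(sequence, k, strand = "both") {
  vocab <- kmer_vocabulary(k)$kmer
  counts <- setNames(integer(length(vocab)), vocab)
  L <- nchar(sequence)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (L >= k) {
    for (s in 1:(L - k + 1)) {
      w <- substr(sequence, s, s + k - 1)
      if (grepl("N", w, fixed = TRUE)) next
      counts[w] <- counts[w] + 1L
      if (strand == "both") {
        rc <- paste(rev(comp[strsplit(w, "")[[1]]]), collapse = "")
        counts[rc] <- counts[rc] + 1L
      }
    }
  }
  counts
}

# Collapsed LDA joint P(z, w) up to a constant, for one assignment vector.
collapsed_log_joint <- function(z, doc, word, T_, W, alpha, beta) {
  lj <- 0
  for (d in unique(doc)) {
    ndj <- tabulate(z[doc == d], nbins = T_)
    lj <- lj + sum(lgamma(alpha + ndj)) - lgamma(T_ * alpha + sum(ndj))
  }
  for (j in seq_len(T_)) {
    njw <- tabulate(word[z == j], nbins = W)
    lj <- lj + sum(lgamma(beta + njw)) - lgamma(W * beta + sum(njw))
  }
  lj
}

# Exhaustive posterior over all T_^N assignments; returns the N x N matrix of
# pairwise topic-co-assignment probabilities.
enumerate_coassignment <- function(doc, word, T_, W, alpha, beta) {
  N <- length(doc)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(T_)), N)))
  lw <- apply(grid, 1, collapsed_log_joint, doc = doc, word = word,
              T_ = T_, W = W, alpha = alpha, beta = beta)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  co <- matrix(0, N, N)
  for (r in seq_len(nrow(grid))) {
    same <- outer(grid[r, ], grid[r, ], "==")
    co <- co + w[r] * same
  }
  co
}

# Co-assignment frequencies from saved Gibbs samples (rows = sweeps).
sample_coassignment <- function(z_samples) {
  N <- ncol(z_samples)
  co <- matrix(0, N, N)
  for (r in seq_len(nrow(z_samples))) {
    co <- co + outer(z_samples[r, ], z_samples[r, ], "==")
  }
  co / nrow(z_samples)
}

# Plain K-medians under Manhattan distance from given initial centroids.
kmedians_oracle <- function(X, init_centroids, max_iter = 100, tol = 1e-6) {
  C <- init_centroids
  K <- nrow(C)
  assign <- integer(nrow(X))
  for (it in seq_len(max_iter)) {
    d <- sapply(seq_len(K), function(i) rowSums(abs(sweep(X, 2, C[i, ]))))
    assign <- max.col(-d, ties.method = "first")
    C_new <- C
    for (i in seq_len(K)) {
      m <- X[assign == i, , drop = FALSE]
      if (nrow(m) > 0) C_new[i, ] <- apply(m, 2, median)
    }
    if (max(abs(C_new - C)) < tol) {
      C <- C_new
      break
    }
    C <- C_new
  }
  d <- sapply(seq_len(K), function(i) rowSums(abs(sweep(X, 2, C[i, ]))))
  list(assign = max.col(-d, ties.method = "first"), centroids = C)
}

# Loop-based precision / sensitivity.
brute_precision <- function(R) {
  top <- 0
  for (i in seq_len(nrow(R))) top <- top + max(R[i, ])
  top / sum(R)
}
brute_sensitivity <- function(R, unclassified = 0) {
  top <- 0
  for (j in seq_len(ncol(R))) top <- top + max(R[, j])
  top / (sum(R) + unclassified)
}

# Random reads over ACGT (optionally with Ns).
random_read <- function(L, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# Two well-separated clouds on the topic simplex.
separable_clouds <- function(n_per = 25, n_dim = 3, seed = 42) {
  set.seed(seed)
  a <- cbind(runif(n_per, 0.8, 0.95))
  X1 <- cbind(a, (1 - a) / 2, (1 - a) / 2)
  b <- cbind(runif(n_per, 0.8, 0.95))
  X2 <- cbind((1 - b) / 2, b, (1 - b) / 2)
  X <- rbind(X1, X2)[, seq_len(n_dim), drop = FALSE]
  rownames(X) <- paste0("p", seq_len(2 * n_per))
  list(X = X, label = rep(c("a", "b"), each = n_per))
}
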