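# Small controlled corpora: forward-strand homopolymer reads give exact token
# streams (a read of length L contributes L - 3 copies of one 4-mer).
toy_corpus <- function(seqs) {
  kmer_corpus(tibble::tibble(id = paste0("d", seq_along(seqs)), sequence = seqs),
              k = 4, strand = "forward")
}

test_that("count tables are consistent with assignments after sampling", {
  cp <- toy_corpus(c("AAAAAA", "CCCCCCC", "ACGTACGT"))
  fit <- fit_lda(cp, topics = 3, sweeps = 25, burn_in = 5, seed = 3)
  expect_equal(unname(rowSums(fit$ndj)), unname(cp$n_tokens))
  expect_equal(unname(rowSums(fit$njw)), fit$nj)
  expect_equal(sum(fit$nj), sum(cp$n_tokens))
  expect_true(all(fit$z >= 0 & fit$z < 3))
  # tables re-derivable from z
  doc <- rep(seq_along(cp$id), cp$n_tokens)
  expect_equal(unname(fit$ndj),
               unname(t(sapply(seq_along(cp$id),
                               function(d) tabulate(fit$z[doc == d] + 1, 3)))))
})

test_that("a single topic forces theta = 1 for every read", {
  cp <- toy_corpus(c("AAAAAA", "CCCCC"))
  fit <- fit_lda(cp, topics = 1, sweeps = 10, burn_in = 2, seed = 1)
  expect_equal(unname(fit$theta[, 1]), c(1, 1))
  expect_true(all(fit$z == 0))
})

test_that("theta and phi lie on the probability simplex", {
  cp <- toy_corpus(c("AAAAAAACGT", "CCCCCGTACG", "TTTTTTTT"))
  fit <- fit_lda(cp, topics = 4, sweeps = 40, burn_in = 10, seed = 9)
  expect_equal(unname(rowSums(fit$theta)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(rowSums(fit$phi)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(fit$theta > 0) && all(fit$phi > 0))
  # topic space is a dimension reduction of the 256-mer space
  expect_lt(ncol(fit$theta), fit$n_words)
})

test_that("identical seed and corpus reproduce bitwise-identical output", {
  cp <- toy_corpus(c("AAAAAAGGG", "CCCCCTTTT"))
  f1 <- fit_lda(cp, topics = 3, sweeps = 60, burn_in = 20, seed = 77)
  f2 <- fit_lda(cp, topics = 3, sweeps = 60, burn_in = 20, seed = 77)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$z, f2$z)
  f3 <- fit_lda(cp, topics = 3, sweeps = 60, burn_in = 20, seed = 78)
  expect_false(identical(f1$z, f3$z))
})

test_that("the conditional is symmetric for a fresh token under symmetric priors", {
  # one document, one token: nothing else is assigned, so both topics tie
  cp <- toy_corpus("AAAA")
  fit <- fit_lda(cp, topics = 2, sweeps = 1, burn_in = 0, seed = 2)
  expect_equal(lda_conditional(fit, cp, 1, 1), c(0.5, 0.5))
})

test_that("the conditional matches a longhand evaluation on a two-token document", {
  cp <- toy_corpus("AAAAA") # two tokens of AAAA in one document
  fit <- fit_lda(cp, topics = 2, sweeps = 1, burn_in = 0, seed = 4)
  a <- fit$alpha; b <- fit$beta; W <- fit$n_words
  z1 <- fit$z[1] + 1 # the other token's topic
  # decrement token 2; counts seen by it are those of token 1 only
  njw <- c(0, 0); njw[z1] <- 1
  ndj <- c(0, 0); ndj[z1] <- 1
  nj <- njw
  hand <- (b + njw) / (W * b + nj) * (a + ndj) / (2 * a + 1)
  expect_equal(lda_conditional(fit, cp, 1, 2), hand / sum(hand))
})

test_that("the conditional is proportional to the collapsed joint ratio", {
  cp <- toy_corpus(c("AAAAA", "TTTT", "ACGT")) # 2 + 1 + 1 tokens
  T_ <- 2
  fit <- fit_lda(cp, topics = T_, sweeps = 3, burn_in = 0, seed = 6)
  doc <- rep(seq_along(cp$id), cp$n_tokens)
  word <- unlist(cp$tokens)
  offs <- c(0, cumsum(cp$n_tokens))
  for (d in seq_along(cp$id)) {
    for (i in seq_len(cp$n_tokens[d])) {
      tok <- offs[d] + i
      joint <- vapply(seq_len(T_), function(j) {
        z <- fit$z + 1
        z[tok] <- j
        collapsed_log_joint(z, doc, word, T_, 256, fit$alpha, fit$beta)
      }, numeric(1))
      expected <- exp(joint - max(joint))
      expected <- expected / sum(expected)
      expect_equal(lda_conditional(fit, cp, d, i), expected, tolerance = 1e-10)
    }
  }
})

test_that("posterior co-assignment from Gibbs matches exhaustive enumeration", {
  # 3 documents, 2 + 1 + 1 tokens: 2^4 assignments enumerable
  cp <- toy_corpus(c("AAAAA", "TTTT", "ACGT"))
  expect_equal(unname(cp$n_tokens), c(2L, 1L, 1L))
  fit <- fit_lda(cp, topics = 2, sweeps = 11000, burn_in = 1000, seed = 13,
                 save_samples = TRUE)
  doc <- rep(seq_along(cp$id), cp$n_tokens)
  word <- unlist(cp$tokens)
  exact <- enumerate_coassignment(doc, word, 2, 256, 0.1, 0.01)
  approx <- sample_coassignment(fit$z_samples)
  expect_lt(max(abs(exact - approx)), 0.03)
})

test_that("documents of same-word token blocks co-assign as the enumerated posterior", {
  # two 2-token homopolymer documents: a near-bimodal posterior whose modes a
  # single chain switches between slowly, so co-assignment is estimated by
  # averaging independent seeded chains
  cp <- toy_corpus(c("AAAAA", "TTTTT"))
  doc <- rep(seq_along(cp$id), cp$n_tokens)
  word <- unlist(cp$tokens)
  exact <- enumerate_coassignment(doc, word, 2, 256, 0.1, 0.01)
  co <- matrix(0, 4, 4)
  for (s in 1:10) {
    fit <- fit_lda(cp, topics = 2, sweeps = 6000, burn_in = 1000,
                   seed = 100 + s, save_samples = TRUE)
    co <- co + sample_coassignment(fit$z_samples)
  }
  expect_lt(max(abs(exact - co / 10)), 0.05)
})

test_that("relabeling the k-mers of a mirror-image corpus leaves inference invariant", {
  cp1 <- toy_corpus(c("AAAAA", "TTTT", "ACGT"))
  cp2 <- toy_corpus(c("TTTTT", "AAAA", "ACGT")) # A <-> T relabeled
  f1 <- fit_lda(cp1, topics = 2, sweeps = 16000, burn_in = 1000, seed = 5,
                save_samples = TRUE)
  f2 <- fit_lda(cp2, topics = 2, sweeps = 16000, burn_in = 1000, seed = 55,
                save_samples = TRUE)
  expect_lt(max(abs(sample_coassignment(f1$z_samples) -
                    sample_coassignment(f2$z_samples))), 0.03)
})

test_that("log-joint diagnostic is recorded per sweep and finite", {
  cp <- toy_corpus(c("AAAAAAGG", "CCCCC"))
  fit <- fit_lda(cp, topics = 2, sweeps = 30, burn_in = 10, seed = 8,
                 track_logjoint = TRUE)
  expect_length(fit$logjoint, 30)
  expect_true(all(is.finite(fit$logjoint)))
})

test_that("tidiers expose theta and phi in long and wide form", {
  cp <- toy_corpus(c("AAAAAA", "CCCCC"))
  fit <- fit_lda(cp, topics = 3, sweeps = 20, burn_in = 5, seed = 2)
  th <- tidy(fit, "theta")
  expect_named(th, c("id", "topic", "theta"))
  expect_equal(nrow(th), 2 * 3)
  ph <- tidy(fit, "phi")
  expect_named(ph, c("topic", "kmer", "phi"))
  expect_equal(nrow(ph), 3 * 256)
  wide <- augment(fit)
  expect_equal(dim(wide), c(2L, 4L))
  expect_equal(glance(fit)$n_tokens, sum(cp$n_tokens))
})

test_that("invalid sampler settings are rejected", {
  cp <- toy_corpus("AAAAAA")
  expect_error(fit_lda(cp, topics = 2, alpha = 0), "positive")
  expect_error(fit_lda(cp, topics = 2, sweeps = 10, burn_in = 10), "burn_in")
  expect_error(fit_lda(list(), topics = 2), "kmer_corpus")
})
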