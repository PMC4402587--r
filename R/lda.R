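#' Fit an LDA topic model to a k-mer corpus by collapsed Gibbs sampling
#'
#' Reads are treated as documents and k-mer occurrences as words. The sampler
#' integrates out the topic and word distributions and resamples every token's
#' topic once per sweep from its full conditional
#' \deqn{P(z_i = j \mid \cdot) \propto
#'   \frac{\beta + n^{w_i}_{-i,j}}{W\beta + n^{*}_{-i,j}} \cdot
#'   \frac{\alpha + n^{d}_{-i,j}}{T\alpha + n^{d}_{-i,*}}}
#' under symmetric Dirichlet priors. After the final sweep the per-read topic
#' distribution and per-topic word distribution are read off the count tables:
#' \eqn{\theta_{dj} = (n_{dj} + \alpha)/(N_d + T\alpha)} and
#' \eqn{\phi_{jw} = (n_{jw} + \beta)/(n_j + W\beta)}. A single final-state
#' estimate is used rather than an average over post-burn-in samples, which
#' would mix topic labels across sweeps (label switching); `burn_in` is a
#' convergence allowance, and the optional log-joint trace is the convergence
#' diagnostic.
#'
#' @param corpus A [kmer_corpus()].
#' @param topics Number of latent topics T (default 20; 100 is the recommended
#'   setting for large or real datasets).
#' @param alpha Symmetric Dirichlet prior on per-read topic proportions
#'   (default 0.1).
#' @param beta Symmetric Dirichlet prior on per-topic word proportions
#'   (default 0.01).
#' @param sweeps Total Gibbs sweeps (default 1000).
#' @param burn_in Sweeps regarded as burn-in (default 500); must be smaller
#'   than `sweeps`. Only stored samples and diagnostics distinguish burn-in.
#' @param seed Integer seed; identical seed and corpus give bit-identical
#'   output.
#' @param save_samples If `TRUE`, keep the token-topic assignment after every
#'   post-burn-in sweep (memory grows with tokens x sweeps; meant for small
#'   corpora and diagnostics).
#' @param track_logjoint If `TRUE`, record the collapsed log-joint
#'   \eqn{\log P(z, w)} after every sweep.
#' @return An object of class `tm_lda`: list with `theta` (reads-by-topics
#'   matrix, rows on the simplex), `phi` (topics-by-words matrix), the count
#'   tables (`ndj`, `njw`, `nj`, `nd`), token assignments `z`, the settings,
#'   and optionally `z_samples` / `logjoint`.
#' @examples
#' reads <- tibble::tibble(id = c("a", "b"),
#'                         sequence = c("ACGTACGTACGT", "TTTTTTTTTTTT"))
#' fit <- fit_lda(kmer_corpus(reads), topics = 2, sweeps = 50, burn_in = 10,
#'                seed = 1)
#' rowSums(fit$theta)
#' @export
fit_lda <- function(corpus, topics = 20, alpha = 0.1, beta = 0.01,
                    sweeps = 1000, burn_in = 500, seed = NULL,
                    save_samples = FALSE, track_logjoint = FALSE) {
  if (!inherits(corpus, "kmer_corpus")) abort("`corpus` must be a kmer_corpus")
  if (topics < 1 || topics != round(topics)) abort("`topics` must be a positive integer")
  if (alpha <= 0 || beta <= 0) abort("`alpha` and `beta` must be positive")
  if (sweeps < 1) abort("`sweeps` must be >= 1")
  if (burn_in < 0 || burn_in >= sweeps) abort("`burn_in` must satisfy 0 <= burn_in < sweeps")
  total_tokens <- sum(corpus$n_tokens)
  if (total_tokens == 0) abort("corpus has no tokens")

  doc <- rep.int(seq_along(corpus$id), corpus$n_tokens) - 1L
  word <- unlist(corpus$tokens, use.names = FALSE) - 1L
  W <- nrow(corpus$vocab)

  with_seed(seed, {
    res <- gibbs_lda_cpp(doc, word, length(corpus$id), W, as.integer(topics),
                         alpha, beta, as.integer(sweeps), as.integer(burn_in),
                         save_samples, track_logjoint)
  })

  theta <- (res$ndj + alpha) / (corpus$n_tokens + topics * alpha)
  rownames(theta) <- corpus$id
  colnames(theta) <- paste0("topic_", seq_len(topics))
  phi <- (res$njw + beta) / (res$nj + W * beta)
  rownames(phi) <- colnames(theta)
  colnames(phi) <- corpus$vocab$kmer

  structure(
    list(theta = theta, phi = phi,
         z = res$z, ndj = res$ndj, njw = res$njw, nj = res$nj, nd = res$nd,
         z_samples = res$z_samples, logjoint = res$logjoint,
         id = corpus$id, topics = as.integer(topics), n_words = W,
         alpha = alpha, beta = beta, sweeps = sweeps, burn_in = burn_in,
         seed = seed),
    class = "tm_lda"
  )
}

#' Full conditional of one token's topic assignment
#'
#' Evaluates, for every topic j, the (normalized) conditional probability that
#' token `i` of read `d` belongs to topic j given all other assignments —
#' the quantity the collapsed Gibbs sampler draws from. Exposed for
#' inspection and testing; the fitting path evaluates it in compiled code.
#'
#' @param fit A `tm_lda` object (its count tables define the state).
#' @param corpus The corpus the model was fitted to.
#' @param d Read index (1-based).
#' @param i Token position within read `d` (1-based).
#' @return Numeric vector of length `topics`, summing to 1.
#' @export
lda_conditional <- function(fit, corpus, d, i) {
  T_ <- fit$topics
  W <- fit$n_words
  w <- corpus$tokens[[d]][i]
  offs <- c(0L, cumsum(corpus$n_tokens))
  t_cur <- fit$z[offs[d] + i] + 1L
  njw <- fit$njw[, w]
  njw[t_cur] <- njw[t_cur] - 1L
  nj <- fit$nj
  nj[t_cur] <- nj[t_cur] - 1L
  ndj <- fit$ndj[d, ]
  ndj[t_cur] <- ndj[t_cur] - 1L
  nd <- fit$nd[d] - 1L
  p <- (fit$beta + njw) / (W * fit$beta + nj) *
    (fit$alpha + ndj) / (T_ * fit$alpha + nd)
  p / sum(p)
}

#' @export
print.tm_lda <- function(x, ...) {
  cat(sprintf("<tm_lda> %d reads, %d topics, %d-word vocabulary\n",
              nrow(x$theta), x$topics, x$n_words))
  cat(sprintf("  alpha = %g, beta = %g, %d sweeps (%d burn-in)\n",
              x$alpha, x$beta, x$sweeps, x$burn_in))
  invisible(x)
}

#' Tidy an LDA fit
#'
#' @param x A `tm_lda` object.
#' @param matrix `"theta"` for per-read topic distributions (columns `id`,
#'   `topic`, `theta`) or `"phi"` for per-topic k-mer distributions (columns
#'   `topic`, `kmer`, `phi`).
#' @param ... Unused.
#' @return A long tibble.
#' @export
tidy.tm_lda <- function(x, matrix = c("theta", "phi"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "theta") {
    as_tibble(x$theta, rownames = "id") |>
      tidyr::pivot_longer(-"id", names_to = "topic", values_to = "theta",
                          names_prefix = "topic_", names_transform = as.integer)
  } else {
    as_tibble(x$phi, rownames = "topic") |>
      tidyr::pivot_longer(-"topic", names_to = "kmer", values_to = "phi") |>
      dplyr::mutate(topic = as.integer(sub("^topic_", "", .data$topic)))
  }
}

#' One-row summary of an LDA fit
#'
#' @param x A `tm_lda` object.
#' @param ... Unused.
#' @export
glance.tm_lda <- function(x, ...) {
  tibble(n_reads = nrow(x$theta), topics = x$topics, n_words = x$n_words,
         n_tokens = sum(x$nd), alpha = x$alpha, beta = x$beta,
         sweeps = x$sweeps, burn_in = x$burn_in,
         log_joint = if (!is.null(x$logjoint)) x$logjoint[x$sweeps] else NA_real_)
}

#' Per-read topic distributions as a wide tibble
#'
#' @param x A `tm_lda` object.
#' @param ... Unused.
#' @return Tibble with `id` and one `topic_*` column per topic; the hand-off
#'   to [skwic()].
#' @export
augment.tm_lda <- function(x, ...) {
  as_tibble(x$theta, rownames = "id")
}

#' Write the read-by-topic matrix as TSV
#'
#' @param fit A `tm_lda` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_theta <- function(fit, path) {
  utils::write.table(data.frame(id = rownames(fit$theta), fit$theta,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the topic-by-kmer matrix as TSV
#'
#' @param fit A `tm_lda` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phi <- function(fit, path) {
  utils::write.table(data.frame(topic = rownames(fit$phi), fit$phi,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
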