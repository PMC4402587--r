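#' Bin metagenomic reads: k-mers -> topics -> SKWIC
#'
#' Runs the full three-step pipeline: tetranucleotide counting
#' ([kmer_corpus()]), topic inference by collapsed Gibbs sampling
#' ([fit_lda()]), and feature-weighted clustering of the per-read topic
#' distributions ([skwic()]). When truth labels are supplied the binning is
#' scored with [evaluate_binning()]; reads dropped before clustering (no
#' valid k-mer window) count as unclassified there. One pipeline `seed` fans
#' out deterministically to the sampler and the clusterer, so identical
#' inputs and seed reproduce identical assignments.
#'
#' @param reads Tibble with `id` and `sequence` columns ([read_sequences()]
#'   or [simulate_community()] output).
#' @param K Number of clusters (expected species count), at least 2.
#' @param topics Number of latent topics (default 20).
#' @param k k-mer length (default 4).
#' @param strand `"both"` (default) or `"forward"`; see [kmer_counts()].
#' @param alpha,beta,sweeps,burn_in Sampler settings, see [fit_lda()].
#' @param K_delta,max_iter,tol,n_restart Clusterer settings, see [skwic()].
#' @param truth Optional tibble with `id` and `label`; enables scoring.
#' @param seed Integer pipeline seed.
#' @param track_logjoint Record the sampler's log-joint trace (diagnostic).
#' @return An object of class `tm_binning`: list with `assignment` (tibble
#'   `id`, `cluster`), `scores` (one-row tibble or `NULL`), `lda`
#'   (`tm_lda`), `skwic` (`skwic_fit`), `excluded` (degenerate read ids) and
#'   `manifest` (every parameter and derived seed).
#' @examples
#' \donttest{
#' com <- simulate_community(n_species = 2, genome_length = 5000,
#'                           n_reads = 80, read_length_mean = 400,
#'                           divergence = 0.9, seed = 1)
#' res <- bin_reads(com$reads, K = 2, topics = 5, sweeps = 150, burn_in = 50,
#'                  truth = com$truth, seed = 1)
#' res$scores
#' }
#' @export
bin_reads <- function(reads, K, topics = 20, k = 4,
                      strand = c("both", "forward"),
                      alpha = 0.1, beta = 0.01, sweeps = 1000, burn_in = 500,
                      K_delta = 1, max_iter = 100, tol = 1e-6, n_restart = 1,
                      truth = NULL, seed = NULL, track_logjoint = FALSE) {
  strand <- match.arg(strand)
  if (K < 2) abort("`K` must be at least 2: binning needs two or more clusters")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)))
    })
  }
  corpus <- stage("kmer", kmer_corpus(reads, k = k, strand = strand))
  lda <- stage("lda", fit_lda(corpus, topics = topics, alpha = alpha,
                              beta = beta, sweeps = sweeps, burn_in = burn_in,
                              seed = derive_seed(seed, "lda"),
                              track_logjoint = track_logjoint))
  skw <- stage("skwic", skwic(augment(lda), K = K, K_delta = K_delta,
                              max_iter = max_iter, tol = tol,
                              n_restart = n_restart,
                              seed = derive_seed(seed, "skwic")))
  scores <- NULL
  if (!is.null(truth) && nrow(truth) > 0) {
    scores <- stage("evaluate",
                    evaluate_binning(skw$assignment, truth,
                                     unclassified = corpus$excluded))
  } else if (is.null(truth)) {
    message("no truth labels supplied; evaluation skipped")
  }
  manifest <- list(
    k = k, strand = strand, topics = topics, alpha = alpha, beta = beta,
    sweeps = sweeps, burn_in = burn_in, K = K, K_delta = K_delta,
    max_iter = max_iter, tol = tol, n_restart = n_restart, seed = seed,
    seed_lda = derive_seed(seed, "lda"),
    seed_skwic = derive_seed(seed, "skwic"),
    n_reads_in = nrow(reads), n_reads_binned = length(corpus$id),
    n_excluded = length(corpus$excluded), n_tokens = sum(corpus$n_tokens)
  )
  structure(
    list(assignment = skw$assignment, scores = scores, lda = lda, skwic = skw,
         excluded = corpus$excluded, truth = truth, manifest = manifest),
    class = "tm_binning"
  )
}

#' @export
print.tm_binning <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<tm_binning> %d reads -> %d topics -> K = %d clusters (seed %s)\n",
              m$n_reads_binned, m$topics, m$K,
              if (is.null(m$seed)) "none" else m$seed))
  print(table(cluster = x$assignment$cluster))
  if (!is.null(x$scores)) {
    cat(sprintf("precision %.4f  sensitivity %.4f  F1 %.4f\n",
                x$scores$precision, x$scores$sensitivity, x$scores$f1))
  }
  invisible(x)
}

#' Tidy a binning result
#'
#' @param x A `tm_binning`.
#' @param ... Unused.
#' @return The read-level assignment tibble, with the truth label joined when
#'   available.
#' @export
tidy.tm_binning <- function(x, ...) {
  out <- x$assignment
  if (!is.null(x$truth)) {
    out <- dplyr::left_join(out, x$truth, by = "id")
  }
  out
}

#' One-row summary of a binning result
#'
#' @param x A `tm_binning`.
#' @param ... Unused.
#' @export
glance.tm_binning <- function(x, ...) {
  m <- x$manifest
  base <- tibble(n_reads = m$n_reads_binned, n_excluded = m$n_excluded,
                 topics = m$topics, K = m$K, objective = x$skwic$objective)
  if (!is.null(x$scores)) {
    dplyr::bind_cols(base, x$scores[, c("precision", "sensitivity", "f1")])
  } else {
    base
  }
}

#' Write all outputs of a binning run to a directory
#'
#' Writes the assignment TSV, the read-by-topic and topic-by-k-mer matrices,
#' the cluster model dump (centroids, weights, delta, objective trace), the
#' evaluation report when scores exist, and a JSON run manifest recording
#' every parameter and seed.
#'
#' @param x A `tm_binning`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_binning <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_assignment(x, file.path(dir, "assignment.tsv"))
  write_theta(x$lda, file.path(dir, "theta.tsv"))
  write_phi(x$lda, file.path(dir, "phi.tsv"))
  utils::write.table(tidy(x$skwic), file.path(dir, "skwic_model.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(x$skwic$trace) > 0) {
    utils::write.table(
      data.frame(iteration = seq_along(x$skwic$trace), objective = x$skwic$trace),
      file.path(dir, "skwic_objective.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(x$scores)) {
    write_eval_report(x$scores, file.path(dir, "evaluation.tsv"))
  }
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(dir)
}

#' Binning performance across topic counts
#'
#' Reruns topic inference and clustering for each requested number of topics
#' on one shared k-mer corpus, scoring each binning against the truth. Used
#' to examine how the latent dimensionality affects binning quality (too few
#' topics lose composition information; very many add noise).
#'
#' @inheritParams bin_reads
#' @param topic_values Integer vector of topic counts to try (duplicates are
#'   dropped with a warning).
#' @param truth Tibble with `id` and `label`; required.
#' @return A tibble with one row per topic count: `topics`, `precision`,
#'   `sensitivity`, `f1`.
#' @export
topic_sweep <- function(reads, truth, topic_values, K, k = 4,
                        strand = c("both", "forward"),
                        alpha = 0.1, beta = 0.01, sweeps = 1000, burn_in = 500,
                        K_delta = 1, max_iter = 100, tol = 1e-6, n_restart = 1,
                        seed = NULL) {
  strand <- match.arg(strand)
  if (length(topic_values) == 0) abort("`topic_values` must not be empty")
  if (is.null(truth) || nrow(truth) == 0) {
    abort("`topic_sweep()` needs truth labels")
  }
  if (anyDuplicated(topic_values)) {
    warn("duplicate `topic_values` dropped")
    topic_values <- unique(topic_values)
  }
  corpus <- kmer_corpus(reads, k = k, strand = strand)
  purrr::map_dfr(topic_values, function(T_) {
    lda <- fit_lda(corpus, topics = T_, alpha = alpha, beta = beta,
                   sweeps = sweeps, burn_in = burn_in,
                   seed = derive_seed(seed, paste0("lda", T_)))
    skw <- skwic(augment(lda), K = K, K_delta = K_delta, max_iter = max_iter,
                 tol = tol, n_restart = n_restart,
                 seed = derive_seed(seed, paste0("skwic", T_)))
    sc <- evaluate_binning(skw$assignment, truth, unclassified = corpus$excluded)
    tibble(topics = as.integer(T_), precision = sc$precision,
           sensitivity = sc$sensitivity, f1 = sc$f1)
  })
}
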