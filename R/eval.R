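#' Cluster-by-species contingency table
#'
#' Builds the M x N matrix R with \eqn{R_{ij}} = number of reads in cluster i
#' whose true species is j. Cluster and species orders are deterministic
#' (sorted labels), and reads the clusterer excluded (e.g. degenerate reads
#' dropped before clustering) are carried as an `unclassified` count that
#' enters only the sensitivity denominator.
#'
#' @param assignment Tibble with `id` and `cluster` columns.
#' @param truth Tibble with `id` and `label` columns covering every assigned
#'   read.
#' @param unclassified Character vector of read ids excluded from the
#'   clustering output.
#' @return An object of class `binning_contingency`: list with `R` (integer
#'   matrix, rownames = cluster, colnames = species), `unclassified` (count),
#'   `M`, `N`.
#' @examples
#' a <- tibble::tibble(id = c("r1", "r2"), cluster = c(1, 2))
#' t <- tibble::tibble(id = c("r1", "r2"), label = c("sp1", "sp2"))
#' binning_contingency(a, t)$R
#' @export
binning_contingency <- function(assignment, truth, unclassified = character()) {
  if (!all(c("id", "cluster") %in% names(assignment))) {
    abort("`assignment` needs `id` and `cluster` columns")
  }
  check_truth_covers(truth, assignment$id)
  lab <- truth$label[match(assignment$id, truth$id)]
  R <- unclass(table(cluster = as.character(assignment$cluster), species = lab))
  R <- R[order(rownames(R)), order(colnames(R)), drop = FALSE]
  structure(
    list(R = R, unclassified = length(unclassified),
         M = nrow(R), N = ncol(R)),
    class = "binning_contingency"
  )
}

#' @export
print.binning_contingency <- function(x, ...) {
  cat(sprintf("<binning_contingency> %d cluster(s) x %d species, %d read(s), %d unclassified\n",
              x$M, x$N, sum(x$R), x$unclassified))
  print(x$R)
  invisible(x)
}

contingency_matrix <- function(x) {
  if (inherits(x, "binning_contingency")) x$R else as.matrix(x)
}

#' Binning precision
#'
#' \deqn{Pr = \sum_i \max_j R_{ij} \big/ \sum_i \sum_j R_{ij}} — the fraction
#' of clustered reads that belong to their cluster's majority species.
#'
#' @param x A [binning_contingency()] or a nonnegative integer matrix R.
#' @return A number in \[0, 1\].
#' @export
binning_precision <- function(x) {
  R <- contingency_matrix(x)
  if (sum(R) == 0) abort("empty contingency: no classified reads")
  sum(apply(R, 1, max)) / sum(R)
}

#' Binning sensitivity
#'
#' \deqn{Se = \sum_j \max_i R_{ij} \big/ \big(\sum_i \sum_j R_{ij} +
#' \mathrm{unclassified}\big)} — the fraction of all reads recovered in their
#' species' best cluster; reads the clusterer left out inflate the
#' denominator only.
#'
#' @param x A [binning_contingency()] or a nonnegative integer matrix R.
#' @param unclassified Number of unclassified reads (ignored when `x` carries
#'   its own count).
#' @return A number in \[0, 1\].
#' @export
binning_sensitivity <- function(x, unclassified = 0) {
  R <- contingency_matrix(x)
  if (inherits(x, "binning_contingency")) unclassified <- x$unclassified
  if (sum(R) + unclassified == 0) abort("empty contingency: no reads")
  sum(apply(R, 2, max)) / (sum(R) + unclassified)
}

#' F1 measure
#'
#' Harmonic mean \eqn{F1 = 2 \cdot Pr \cdot Se / (Pr + Se)}, defined as 0 at
#' \eqn{Pr = Se = 0} (the limit).
#'
#' @param pr Precision in \[0, 1\].
#' @param se Sensitivity in \[0, 1\].
#' @return A number in \[0, 1\].
#' @examples
#' binning_f1(0.7578, 0.7546)
#' @export
binning_f1 <- function(pr, se) {
  if (any(pr < 0 | pr > 1) || any(se < 0 | se > 1)) {
    abort("`pr` and `se` must lie in [0, 1]")
  }
  ifelse(pr + se == 0, 0, 2 * pr * se / (pr + se))
}

#' Score a binning against truth labels
#'
#' @inheritParams binning_contingency
#' @return A one-row tibble: `precision`, `sensitivity`, `f1`, `n_clusters`,
#'   `n_species`, `n_reads`, `n_unclassified`.
#' @export
evaluate_binning <- function(assignment, truth, unclassified = character()) {
  if (nrow(truth) == 0) abort("truth labels are empty; nothing to evaluate")
  ct <- binning_contingency(assignment, truth, unclassified)
  pr <- binning_precision(ct)
  se <- binning_sensitivity(ct)
  tibble(precision = pr, sensitivity = se, f1 = binning_f1(pr, se),
         n_clusters = ct$M, n_species = ct$N, n_reads = sum(ct$R),
         n_unclassified = ct$unclassified)
}

#' Write an evaluation report as TSV
#'
#' @param scores A tibble as returned by [evaluate_binning()] (a `run` column
#'   is added when absent).
#' @param path Output path.
#' @param run Run identifier recorded in the report.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(scores, path, run = "run") {
  if (!"run" %in% names(scores)) scores <- dplyr::mutate(scores, run = run, .before = 1)
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
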