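#' Cluster topic vectors with SKWIC (feature-weighted K-means)
#'
#' SKWIC minimizes
#' \deqn{J = \sum_{i=1}^{K} \sum_{x_j \in \chi_i} \sum_{k=1}^{n}
#'   v_{ik} D_{ijk} + \sum_{i=1}^{K} \delta_i \sum_{k=1}^{n} v_{ik}^2}
#' subject to \eqn{v_{ik} \in [0,1]} and \eqn{\sum_k v_{ik} = 1}, where
#' \eqn{D_{ijk} = |x_{jk} - c_{ik}|} is the per-dimension Manhattan distance
#' between point j and centroid i. Each cluster learns its own weight over the
#' n feature dimensions (here: topics), so dimensions that discriminate a
#' cluster well dominate its distance. The closed-form weight update is
#' \deqn{v_{ik} = 1/n + \frac{1}{2\delta_i}\sum_{x_j \in \chi_i}
#'   \Big[\sum_l D_{ijl}/n - D_{ijk}\Big]}
#' and the regularizer is rescaled each iteration as
#' \deqn{\delta_i = K_\delta \frac{\sum_{x_j \in \chi_i} \sum_k v_{ik}
#'   D_{ijk}}{\sum_k v_{ik}^2}.}
#'
#' One iteration updates the weights, reassigns points to the cluster with
#' smallest weighted distance, recomputes centroids (per-dimension median,
#' which minimizes the Manhattan within-cluster cost), then updates
#' \eqn{\delta}. Iterations stop when the largest absolute centroid change is
#' below `tol` or `max_iter` is reached; a final assignment pass against the
#' converged centroids and weights is then made. Negative weight updates are
#' clipped to zero and the row renormalized; an emptied cluster is reseeded
#' with the point farthest from its own centroid.
#'
#' @param data A tibble whose first column is `id` and remaining columns are
#'   numeric features (e.g. [augment.tm_lda()] output), or a numeric matrix
#'   with rownames.
#' @param K Number of clusters (the expected species count); at least 2 for
#'   binning, `K = 1` is allowed for degenerate tests.
#' @param K_delta Positive constant scaling the \eqn{\delta_i} update
#'   (default 1).
#' @param max_iter Maximum iterations (default 100).
#' @param tol Convergence threshold on the maximum absolute centroid change
#'   (default 1e-6).
#' @param seed Integer seed for the centroid initialization (K distinct data
#'   points drawn without replacement).
#' @param weighting If `FALSE`, weights stay frozen at 1/n and delta updates
#'   are skipped: the algorithm reduces to K-medians under Manhattan distance
#'   (useful for ablation).
#' @param centroid `"median"` (default; Manhattan-optimal) or `"mean"`.
#' @param n_restart Number of seeded restarts; the fit with the lowest final
#'   objective J is kept.
#' @param init Optional integer vector of K row indices to use as initial
#'   centroids (overrides random initialization; forces `n_restart = 1`).
#' @return An object of class `skwic_fit`: list with `assignment` (tibble
#'   `id`, `cluster`), `centroids` (K x n), `weights` (K x n, rows on the
#'   simplex), `delta`, `objective`, `trace` (per-iteration J), `weight_history`
#'   (per-iteration weight matrices), `iterations`, `converged`, settings.
#' @examples
#' pts <- tibble::tibble(id = paste0("r", 1:6),
#'                       d1 = c(0, 0.1, 0.05, 0.9, 1, 0.95),
#'                       d2 = 1 - c(0, 0.1, 0.05, 0.9, 1, 0.95))
#' fit <- skwic(pts, K = 2, seed = 1)
#' fit$assignment
#' @export
skwic <- function(data, K, K_delta = 1, max_iter = 100, tol = 1e-6,
                  seed = NULL, weighting = TRUE,
                  centroid = c("median", "mean"), n_restart = 1,
                  init = NULL) {
  centroid <- match.arg(centroid)
  xm <- as_feature_matrix(data)
  X <- xm$X
  if (!is.numeric(K) || length(K) != 1 || K != round(K) || K < 1) {
    abort("`K` must be a single positive integer")
  }
  K <- as.integer(K)
  if (K_delta <= 0) abort("`K_delta` must be positive")
  if (tol <= 0) abort("`tol` must be positive")
  n_distinct <- nrow(unique(X))
  if (n_distinct < K) {
    abort(sprintf("need at least K = %d distinct points, have %d", K, n_distinct))
  }
  if (!is.null(init)) n_restart <- 1L

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restart)) {
      fit <- skwic_once(X, K, K_delta, max_iter, tol, weighting, centroid, init)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })

  best$assignment <- tibble(id = xm$id, cluster = best$cluster)
  best$cluster <- NULL
  best$K <- K
  best$K_delta <- K_delta
  best$weighting <- weighting
  best$centroid_rule <- centroid
  best$seed <- seed
  class(best) <- "skwic_fit"
  best
}

as_feature_matrix <- function(data) {
  if (is.matrix(data)) {
    id <- rownames(data)
    if (is.null(id)) id <- as.character(seq_len(nrow(data)))
    return(list(X = data, id = id))
  }
  if (!is.data.frame(data)) abort("`data` must be a data frame or matrix")
  num <- vapply(data, is.numeric, logical(1))
  id <- if ("id" %in% names(data)) as.character(data$id) else as.character(seq_len(nrow(data)))
  X <- as.matrix(data[, num, drop = FALSE])
  if (ncol(X) == 0) abort("`data` has no numeric feature columns")
  rownames(X) <- id
  list(X = X, id = id)
}

skwic_once <- function(X, K, K_delta, max_iter, tol, weighting, centroid, init) {
  n <- ncol(X)
  D_pts <- nrow(X)
  if (is.null(init)) {
    # sample distinct points as seeds
    ord <- sample.int(D_pts)
    keep <- ord[!duplicated(X[ord, , drop = FALSE])][seq_len(K)]
  } else {
    if (length(init) != K) abort("`init` must give K row indices")
    keep <- as.integer(init)
  }
  C <- X[keep, , drop = FALSE]
  rownames(C) <- NULL
  v <- matrix(1 / n, K, n)
  assign <- assign_clusters(X, C, v)
  delta <- skwic_update_delta(X, C, v, assign, K_delta,
                              prev_delta = rep(1, K))
  trace <- numeric(0)
  weight_history <- list()
  converged <- FALSE
  iter <- 0L
  clip_events <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    if (weighting) {
      upd <- skwic_update_weights(X, C, assign, delta, details = TRUE)
      v <- upd$v
      clip_events <- clip_events + upd$clipped
    }
    assign <- assign_clusters(X, C, v)
    # reseed empty clusters with the point farthest from its current centroid
    empty <- setdiff(seq_len(K), unique(assign))
    for (i in empty) {
      wd <- weighted_distances(X, C, v)
      far <- which.max(wd[cbind(seq_len(nrow(X)), assign)])
      C[i, ] <- X[far, ]
      assign[far] <- i
    }
    C_new <- update_centroids(X, assign, K, C, centroid)
    if (weighting) {
      delta <- skwic_update_delta(X, C_new, v, assign, K_delta, prev_delta = delta)
    }
    shift <- max(abs(C_new - C))
    C <- C_new
    trace <- c(trace, skwic_objective(X, C, v, assign, delta))
    weight_history[[iter]] <- v
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  # final assignment against the converged centroids and weights, so no point
  # can lower its weighted distance by switching clusters
  assign <- assign_clusters(X, C, v)
  obj <- skwic_objective(X, C, v, assign, delta)
  if (clip_events > 0) {
    warn(sprintf("negative feature weights clipped to 0 in %d update(s)", clip_events))
  }
  list(cluster = assign, centroids = C, weights = v, delta = delta,
       objective = obj, trace = trace, weight_history = weight_history,
       iterations = iter, converged = converged)
}

#' Per-dimension Manhattan distance to a centroid
#'
#' @param x Numeric vector (one point).
#' @param c Numeric vector (one centroid) of the same length.
#' @return Nonnegative vector `|x - c|`, one entry per dimension.
#' @export
per_dim_distance <- function(x, c) {
  if (length(x) != length(c)) abort("`x` and `c` must have equal length")
  abs(x - c)
}

# |X - C[i,]| for all points: D_pts x n
dist_to_centroid <- function(X, ci) {
  abs(sweep(X, 2, ci))
}

# weighted Manhattan distance of every point to every centroid: D_pts x K
weighted_distances <- function(X, C, v) {
  vapply(seq_len(nrow(C)),
         function(i) dist_to_centroid(X, C[i, ]) %*% v[i, ],
         numeric(nrow(X)))
}

# nearest cluster, ties broken toward the lowest cluster index (max.col with
# "first" on the negated distances)
assign_clusters <- function(X, C, v) {
  wd <- weighted_distances(X, C, v)
  max.col(-wd, ties.method = "first")
}

update_centroids <- function(X, assign, K, C_old, centroid) {
  C <- C_old
  for (i in seq_len(K)) {
    members <- X[assign == i, , drop = FALSE]
    if (nrow(members) == 0) next
    C[i, ] <- if (centroid == "median") apply(members, 2, median) else colMeans(members)
  }
  C
}

#' SKWIC weight update
#'
#' Closed-form update of the per-cluster feature weights; negative entries are
#' clipped to zero and the row renormalized to the simplex, and rows of empty
#' clusters are reset to uniform.
#'
#' @param X Numeric data matrix (points x dimensions).
#' @param C Centroid matrix (K x dimensions).
#' @param assign Integer cluster assignment per point.
#' @param delta Length-K positive regularizers.
#' @param details If `TRUE`, also return the number of clipped rows.
#' @return The K x n weight matrix (or a list with `v` and `clipped`).
#' @export
skwic_update_weights <- function(X, C, assign, delta, details = FALSE) {
  K <- nrow(C)
  n <- ncol(C)
  v <- matrix(1 / n, K, n)
  clipped <- 0L
  for (i in seq_len(K)) {
    members <- X[assign == i, , drop = FALSE]
    if (nrow(members) == 0) next
    Dk <- colSums(dist_to_centroid(members, C[i, ]))
    vi <- 1 / n + (sum(Dk) / n - Dk) / (2 * delta[i])
    if (any(vi < 0)) {
      clipped <- clipped + 1L
      vi[vi < 0] <- 0
      vi <- vi / sum(vi)
    }
    v[i, ] <- vi
  }
  if (details) list(v = v, clipped = clipped) else v
}

#' SKWIC regularizer update
#'
#' Rescales each cluster's \eqn{\delta_i} by the ratio of its weighted
#' within-cluster dispersion to the squared norm of its weights, times
#' `K_delta`. Empty clusters keep their previous value; a perfectly tight
#' cluster gets a small positive floor so the weight update stays defined.
#'
#' @inheritParams skwic_update_weights
#' @param v Current K x n weight matrix.
#' @param K_delta Positive scale constant.
#' @param prev_delta Length-K previous values (kept for empty clusters).
#' @return Length-K positive vector.
#' @export
skwic_update_delta <- function(X, C, v, assign, K_delta, prev_delta) {
  K <- nrow(C)
  delta <- prev_delta
  for (i in seq_len(K)) {
    members <- X[assign == i, , drop = FALSE]
    if (nrow(members) == 0) next
    Dk <- colSums(dist_to_centroid(members, C[i, ]))
    num <- sum(v[i, ] * Dk)
    delta[i] <- if (num <= 0) 1e-9 else K_delta * num / sum(v[i, ]^2)
  }
  delta
}

skwic_objective <- function(X, C, v, assign, delta) {
  J <- 0
  for (i in seq_len(nrow(C))) {
    members <- X[assign == i, , drop = FALSE]
    if (nrow(members) > 0) {
      J <- J + sum(sweep(dist_to_centroid(members, C[i, ]), 2, v[i, ], "*"))
    }
    J <- J + delta[i] * sum(v[i, ]^2)
  }
  J
}

#' @export
print.skwic_fit <- function(x, ...) {
  cat(sprintf("<skwic_fit> K = %d on %d points (%d dims); J = %.6g; %d iteration(s)%s\n",
              x$K, nrow(x$assignment), ncol(x$centroids), x$objective,
              x$iterations, if (x$converged) ", converged" else ""))
  print(table(cluster = x$assignment$cluster))
  invisible(x)
}

#' Tidy a SKWIC fit
#'
#' @param x A `skwic_fit`.
#' @param ... Unused.
#' @return Long tibble with one row per cluster x dimension: `cluster`,
#'   `dimension`, `centroid`, `weight`, `delta`, `size`.
#' @export
tidy.skwic_fit <- function(x, ...) {
  K <- x$K
  n <- ncol(x$centroids)
  sizes <- tabulate(x$assignment$cluster, nbins = K)
  dims <- colnames(x$centroids)
  if (is.null(dims)) dims <- paste0("dim_", seq_len(n))
  tibble(
    cluster = rep(seq_len(K), each = n),
    dimension = rep(dims, K),
    centroid = as.vector(t(x$centroids)),
    weight = as.vector(t(x$weights)),
    delta = rep(x$delta, each = n),
    size = rep(sizes, each = n)
  )
}

#' One-row summary of a SKWIC fit
#'
#' @param x A `skwic_fit`.
#' @param ... Unused.
#' @export
glance.skwic_fit <- function(x, ...) {
  tibble(K = x$K, n_points = nrow(x$assignment), n_dims = ncol(x$centroids),
         objective = x$objective, iterations = x$iterations,
         converged = x$converged, K_delta = x$K_delta)
}

#' Point-level assignments of a SKWIC fit
#'
#' @param x A `skwic_fit`.
#' @param ... Unused.
#' @return The `id`/`cluster` assignment tibble.
#' @export
augment.skwic_fit <- function(x, ...) {
  x$assignment
}

#' Write a cluster assignment as TSV
#'
#' @param x A `skwic_fit` or `tm_binning` object, or an assignment tibble.
#' @param path Output path (columns: read id, cluster index; no header).
#' @return `path`, invisibly.
#' @export
write_assignment <- function(x, path) {
  a <- if (is.data.frame(x)) x else x$assignment
  utils::write.table(a[, c("id", "cluster")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
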