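test_that("per-dimension distance is the absolute coordinate difference", {
  x <- c(0.3, 0.5, 0.2)
  expect_equal(per_dim_distance(x, x), c(0, 0, 0))
  expect_equal(per_dim_distance(c(0.3, 0), c(0.1, 0))[1], 0.2)
  set.seed(1)
  a <- runif(6); b <- runif(6)
  expect_equal(sum(per_dim_distance(a, b)), sum(abs(a - b)))
  expect_error(per_dim_distance(1:3, 1:2), "equal length")
})

test_that("weight update gives uniform weights for a zero-dispersion cluster", {
  X <- matrix(rep(c(0.2, 0.3, 0.5), 1), 1, 3, byrow = TRUE)
  C <- X
  v <- skwic_update_weights(X, C, assign = 1L, delta = 1)
  expect_equal(v, matrix(1 / 3, 1, 3))
})

test_that("equal within-cluster dispersion across dimensions gives equal weights", {
  # two points symmetric about the centroid in both dimensions
  X <- rbind(c(0, 0), c(2, 2))
  C <- rbind(c(1, 1))
  v <- skwic_update_weights(X, C, assign = c(1L, 1L), delta = 5)
  expect_equal(v, matrix(0.5, 1, 2))
})

test_that("weight update solves the constrained optimality conditions", {
  # minimize sum_k v_k D_k + delta sum_k v_k^2 s.t. sum v = 1: compare the
  # closed form against a numeric optimizer on the reduced parametrization
  set.seed(23)
  X <- matrix(runif(15), 5, 3)
  C <- matrix(colMeans(X), 1)
  delta <- 4 # large enough that no clipping triggers
  v <- skwic_update_weights(X, C, assign = rep(1L, 5), delta = delta)
  expect_true(all(v >= 0))
  Dk <- colSums(abs(sweep(X, 2, C[1, ])))
  obj <- function(v12) {
    vv <- c(v12, 1 - sum(v12))
    sum(vv * Dk) + delta * sum(vv^2)
  }
  opt <- optim(v[1, 1:2], obj, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(v[1, ]), unname(c(opt$par, 1 - sum(opt$par))),
               tolerance = 1e-5)
  # and the row satisfies the simplex constraint
  expect_equal(sum(v), 1)
})

test_that("negative weight updates are clipped to zero and renormalized", {
  # tiny delta makes the raw update leave [0, 1]
  set.seed(3)
  X <- matrix(runif(12), 4, 3)
  C <- matrix(colMeans(X), 1)
  v <- skwic_update_weights(X, C, assign = rep(1L, 4), delta = 1e-4)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(sum(v), 1)
  expect_true(any(v[1, ] == 0))
})

test_that("delta update matches hand algebra for uniform weights", {
  set.seed(7)
  X <- matrix(runif(20), 5, 4)
  C <- matrix(colMeans(X), 1)
  n <- 4
  v <- matrix(1 / n, 1, n)
  S <- sum(abs(sweep(X, 2, C[1, ]))) # total within-cluster dispersion
  d1 <- skwic_update_delta(X, C, v, assign = rep(1L, 5), K_delta = 1,
                           prev_delta = 1)
  expect_equal(d1, S) # K_delta * (S/n) / (n * (1/n)^2) = K_delta * S
  d2 <- skwic_update_delta(X, C, v, assign = rep(1L, 5), K_delta = 2,
                           prev_delta = 1)
  expect_equal(d2, 2 * S) # linear in K_delta
})

test_that("delta keeps its previous value for empty clusters and floors at tightness", {
  X <- rbind(c(0, 0), c(1, 1))
  C <- rbind(c(0, 0), c(5, 5))
  v <- matrix(0.5, 2, 2)
  d <- skwic_update_delta(X, C, v, assign = c(1L, 1L), K_delta = 1,
                          prev_delta = c(9, 9))
  expect_equal(d[2], 9) # cluster 2 empty: unchanged
  # perfectly tight cluster: positive floor keeps Eq-style weight update defined
  d0 <- skwic_update_delta(rbind(c(1, 2)), rbind(c(1, 2)), matrix(0.5, 1, 2),
                           assign = 1L, K_delta = 1, prev_delta = 1)
  expect_equal(d0, 1e-9)
})

test_that("well-separated clouds are partitioned perfectly", {
  sc <- separable_clouds(n_per = 25)
  fit <- skwic(sc$X, K = 2, seed = 5)
  truth <- tibble::tibble(id = rownames(sc$X), label = sc$label)
  scores <- evaluate_binning(fit$assignment, truth)
  expect_equal(scores$f1, 1)
})

test_that("weight rows stay on the simplex after every iteration", {
  set.seed(9)
  X <- matrix(runif(120), 40, 3)
  fit <- skwic(X, K = 3, seed = 9)
  for (v in fit$weight_history) {
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(unname(rowSums(v)), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("with frozen uniform weights the fit reduces to Manhattan K-medians", {
  set.seed(17)
  X <- matrix(runif(100), 50, 2)
  init <- c(4L, 29L, 41L)
  fit <- skwic(X, K = 3, weighting = FALSE, init = init, seed = 1)
  oracle <- kmedians_oracle(X, X[init, , drop = FALSE])
  expect_equal(fit$assignment$cluster, oracle$assign)
  expect_equal(unname(fit$centroids), unname(oracle$centroids))
  expect_equal(unname(fit$weights), matrix(0.5, 3, 2))
})

test_that("no point can improve its weighted distance by switching clusters", {
  set.seed(33)
  X <- matrix(runif(90), 30, 3)
  fit <- skwic(X, K = 3, seed = 33)
  wd <- sapply(seq_len(3), function(i) {
    rowSums(abs(sweep(X, 2, fit$centroids[i, ])) %*% diag(fit$weights[i, ]))
  })
  best <- max.col(-wd, ties.method = "first")
  expect_equal(fit$assignment$cluster, best)
})

test_that("identical seed and data give identical fits", {
  set.seed(2)
  X <- matrix(runif(60), 20, 3)
  f1 <- skwic(X, K = 2, seed = 11)
  f2 <- skwic(X, K = 2, seed = 11)
  expect_identical(f1$assignment, f2$assignment)
  expect_identical(f1$centroids, f2$centroids)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$delta, f2$delta)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rep(c(0.5, 0.5), 5), 5, 2, byrow = TRUE)
  expect_error(skwic(X, K = 2), "distinct points")
  expect_error(skwic(matrix(runif(10), 5, 2), K = 0), "positive integer")
  expect_error(skwic(tibble::tibble(id = letters[1:3]), K = 2),
               "numeric feature")
})

test_that("K = 1 collapses to the per-dimension median with uniform-ish weights", {
  set.seed(4)
  X <- matrix(runif(30), 10, 3)
  fit <- skwic(X, K = 1, seed = 4)
  expect_true(all(fit$assignment$cluster == 1))
  expect_equal(unname(fit$centroids[1, ]), unname(apply(X, 2, median)))
})

test_that("tidiers summarize the fit", {
  sc <- separable_clouds(10)
  fit <- skwic(sc$X, K = 2, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 3)
  expect_equal(sum(td$size) / 3, 20)
  g <- glance(fit)
  expect_equal(g$K, 2L)
  expect_true(g$converged)
  expect_equal(augment(fit), fit$assignment)
})
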