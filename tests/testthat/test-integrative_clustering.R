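test_that("penalized log-likelihood ascends for random data and lambdas", {
  set.seed(21)
  for (r in 1:4) {
    X <- matrix(rnorm(30 * 40), 30, 40,
                dimnames = list(NULL, paste0("s", 1:40)))
    lam <- c(0, 0.1, 0.3, 0.6)[r]
    fit <- icluster_fit(list(X), C = 3, lambda = lam, seed = r,
                        max_iter = 80)
    expect_true(all(diff(fit$loglik_trace) >= -1e-6),
                label = sprintf("ascent at lambda=%.1f", lam))
  }
})

test_that("lambda=0, C=2, single modality recovers the top principal
           direction (probabilistic PCA equivalence)", {
  set.seed(22)
  X <- matrix(rnorm(40 * 60), 40, 60)
  X[1:10, ] <- X[1:10, ] + rep(rnorm(60) * 2, each = 10)
  colnames(X) <- paste0("s", 1:60)
  fit <- icluster_fit(list(X), C = 2, lambda = 0, seed = 1)
  Xs <- t(scale(t(X)))
  # oracle: direct eigendecomposition of the sample covariance
  ev <- eigen(tcrossprod(Xs) / ncol(Xs), symmetric = TRUE)$vectors[, 1]
  scores <- drop(crossprod(Xs, ev))
  cosine <- abs(sum(scores * drop(fit$Z)) /
                  sqrt(sum(scores^2) * sum(fit$Z^2)))
  expect_gte(cosine, 0.99)
})

test_that("exact model data with separated means is recovered (ARI 1)
           and thresholding is monotone in lambda", {
  set.seed(23)
  n <- 90; truth <- rep(1:3, each = 30)
  Z <- matrix(0, 2, n)
  Z[1, truth == 1] <- 4; Z[1, truth == 2] <- -4
  Z[2, truth == 3] <- 4
  W1 <- matrix(rnorm(25 * 2), 25, 2)
  W2 <- matrix(rnorm(35 * 2), 35, 2)
  mk <- function(W, noise) {
    M <- W %*% Z + matrix(rnorm(nrow(W) * n, sd = noise), nrow(W), n)
    colnames(M) <- paste0("s", 1:n); M
  }
  Xl <- list(a = mk(W1, 0.05), b = mk(W2, 0.05))
  fit <- icluster_fit(Xl, C = 3, lambda = 0, seed = 2)
  expect_equal(adjusted_rand_index(fit$labels, truth), 1)
  # labels ordered by decreasing cluster size convention
  expect_equal(which.max(tabulate(fit$labels)), 1L)
  f1 <- icluster_fit(Xl, C = 3, lambda = 0.8, seed = 2)
  nnz <- function(f) sum(abs(do.call(rbind, f$W)) > 1e-10)
  expect_lte(nnz(f1), nnz(fit))
  expect_error(icluster_fit(Xl, C = 1), "C must be")
  bad <- Xl; colnames(bad$b) <- rev(colnames(bad$b))
  expect_error(icluster_fit(bad, C = 3), "sample ids differ")
})

test_that("permuting samples permutes labels identically", {
  set.seed(24)
  X <- matrix(rnorm(30 * 50), 30, 50)
  X[, 1:25] <- X[, 1:25] + 2
  colnames(X) <- paste0("s", 1:50)
  fit <- icluster_fit(list(X), C = 2, lambda = 0, seed = 5)
  perm <- sample(50)
  fit_p <- icluster_fit(list(X[, perm]), C = 2, lambda = 0, seed = 5)
  # same partition of the same sample ids (cluster ids may swap only if
  # sizes tie; compare as partitions)
  expect_equal(
    adjusted_rand_index(fit$labels[colnames(X)[perm]], fit_p$labels), 1)
})

test_that("stability machinery: identical repeats give mean ARI 1,
           ties go to the smaller C", {
  labs <- replicate(4, setNames(rep(1:2, each = 10), paste0("s", 1:20)),
                    simplify = FALSE)
  rep_report <- stability_report(labs)
  expect_equal(rep_report$mean_ari, 1)
  expect_true(isSymmetric(rep_report$pairwise_ari))
  expect_equal(unname(diag(rep_report$pairwise_ari)), rep(1, 4))
  expect_error(stability_report(labs[1]), "fewer than 2")
})

test_that("select_cluster_count prefers the planted cluster number", {
  set.seed(31)
  n <- 120; truth <- rep(1:3, each = 40)
  Z <- rbind(c(-4, 4, 0)[truth], c(0, 0, 5)[truth]) +
    matrix(rnorm(2 * n, sd = 0.3), 2, n)
  mk <- function(p) {
    M <- matrix(rnorm(p * 2), p, 2) %*% Z +
      matrix(rnorm(p * n, sd = 1), p, n)
    colnames(M) <- paste0("s", 1:n); M
  }
  Xl <- list(a = mk(30), b = mk(20))
  sel <- select_cluster_count(Xl, C_candidates = c(3L, 4L),
                              repeats = 5, seed = 31)
  expect_equal(sel$C, 3L)
  expect_gt(sel$mean_ari[["C3"]], 0.8)
})

test_that("tune_lambda defines the grid and flags structureless data", {
  set.seed(26)
  Xn <- list(matrix(rnorm(30 * 60), 30, 60,
                    dimnames = list(NULL, paste0("s", 1:60))))
  tl <- tune_lambda(Xn, C = 3, n_points = 10, repeats = 3, seed = 2)
  expect_equal(tl$grid$lambda, seq(0, 1, length.out = 10))
  expect_true(tl$no_structure)
  expect_error(tune_lambda(Xn, C = 3, repeats = 1), "repeats")
})
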