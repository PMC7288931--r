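# Joint latent-variable integrative clustering (iCluster-style).
#
# Gaussian model per modality t:  X_t = W_t Z + eps_t,
# Z ~ N(0, I_d), eps ~ N(0, Psi_t diagonal), latent dimension
# d = C - 1 for C clusters. Fitted by EM with an L1 penalty on the
# loadings (exact per-feature coordinate-descent lasso in the M-step, so
# the penalized likelihood ascends monotonically); cluster labels come
# from k-means on the columns of E[Z].

#' Fit the penalized joint latent-variable model
#'
#' All modalities must share the same samples (columns). Features are
#' row-standardized internally. The monitored objective is the observed
#' penalized log-likelihood per sample,
#' `loglik/n - lambda * sum(|W|)`, which is nondecreasing across EM
#' iterations (ECM with an exact lasso M-step).
#'
#' @param X_list named list of numeric matrices (features x samples),
#'   one per modality, identical colnames.
#' @param C number of clusters (>= 2); latent dimension is `C - 1`.
#' @param lambda sparsity weight in `[0, 1]`; soft-threshold level in the
#'   M-step scales with `lambda` (0 = no penalty).
#' @param seed seed for the initialization jitter and the k-means
#'   restarts.
#' @param max_iter EM iteration cap (default 200).
#' @param tol relative objective-change stopping tolerance (default 1e-6).
#' @param standardize row-standardize inputs (default TRUE).
#' @return an `integrative_model`: `W` (list per modality), `psi` (list),
#'   `Z` (`d x n` posterior mean), `d`, `C`, `lambda`, `loglik_trace`,
#'   `labels` (named, clusters ordered by decreasing size: 1 = largest).
#' @export
icluster_fit <- function(X_list, C, lambda = 0, seed = 1L,
                         max_iter = 200L, tol = 1e-6,
                         standardize = TRUE) {
  if (C < 2) stop("C must be >= 2")
  stopifnot(is.list(X_list), length(X_list) >= 1)
  if (is.null(names(X_list)))
    names(X_list) <- paste0("mod", seq_along(X_list))
  cols <- lapply(X_list, colnames)
  n <- unique(vapply(X_list, ncol, integer(1)))
  if (length(n) != 1)
    stop("modalities disagree on sample count")
  if (!is.null(cols[[1]])) {
    for (i in seq_along(cols))
      if (!identical(cols[[i]], cols[[1]]))
        stop("sample ids differ between modalities")
  }
  d <- C - 1L
  X <- do.call(rbind, lapply(X_list, function(m) {
    m <- as.matrix(m)
    if (standardize) row_standardize(m) else m
  }))
  p <- nrow(X)
  if (n <= d) stop("need more samples than latent dimensions")
  p_per <- vapply(X_list, nrow, integer(1))
  mod_of <- rep(seq_along(X_list), p_per)

  # init: top-d SVD directions plus a small seeded jitter (the jitter is
  # what makes independently seeded refits genuinely independent)
  set.seed(seed)
  sv <- svd(X, nu = d, nv = 0)
  W <- sv$u %*% diag(sv$d[seq_len(d)] / sqrt(n), d, d)
  W <- W + matrix(rnorm(p * d, sd = 0.05 * sd(W)), p, d)
  psi <- pmax(1 - rowSums(W^2), 0.05)

  sum_x2 <- rowSums(X^2)
  lam_n <- lambda * n                      # penalty on the n-scaled Q
  trace <- numeric(0)
  last <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step
    Wp <- W / psi                          # Psi^{-1} W
    M <- diag(d) + crossprod(W, Wp)        # I + W' Psi^{-1} W
    Minv <- solve(M)
    A <- crossprod(Wp, X)                  # W' Psi^{-1} X   (d x n)
    EZ <- Minv %*% A
    Szz <- n * Minv + tcrossprod(EZ)       # sum_u E[z z']
    B <- tcrossprod(X, EZ)                 # p x d, rows b_i = X_i EZ'
    # M-step, W: per-feature lasso  min (1/2psi) (w'Szz w - 2 b'w) + lam|w|
    # solved by coordinate descent, vectorized across features
    for (pass in seq_len(200L)) {
      delta <- 0
      for (j in seq_len(d)) {
        r_j <- B[, j] - W %*% Szz[, j] + W[, j] * Szz[j, j]
        w_new <- soft_threshold(r_j, lam_n * psi) / Szz[j, j]
        delta <- max(delta, max(abs(w_new - W[, j])))
        W[, j] <- w_new
      }
      if (delta < 1e-10) break
    }
    # M-step, psi
    resid <- sum_x2 - 2 * rowSums(B * W) + rowSums((W %*% Szz) * W)
    psi <- pmax(resid / n, 1e-6)
    # observed penalized log-likelihood per sample (Woodbury)
    Wp <- W / psi
    M <- diag(d) + crossprod(W, Wp)
    A <- crossprod(Wp, X)
    quad <- sum(sum_x2 / psi) - sum(A * (solve(M, A)))
    logdet <- sum(log(psi)) + determinant(M, logarithm = TRUE)$modulus[1]
    ll <- -0.5 * (p * log(2 * pi) + logdet + quad / n)
    obj <- ll - lambda * sum(abs(W))
    trace <- c(trace, obj)
    if (is.finite(last) && abs(obj - last) <= tol * max(abs(last), 1))
      break
    last <- obj
  }
  # final E[Z] and labels
  Wp <- W / psi
  M <- diag(d) + crossprod(W, Wp)
  EZ <- solve(M, crossprod(Wp, X))
  degenerate <- nrow(unique(round(t(EZ), 8))) < C
  if (degenerate) {
    # fully shrunk / collapsed latent space: no usable partition
    labels <- rep(1L, n)
  } else {
    set.seed(seed + 1L)
    km <- kmeans(t(EZ), centers = C, nstart = 20, iter.max = 100)
    labels <- relabel_by_size(km$cluster)
  }
  names(labels) <- cols[[1]] %||% paste0("S", seq_len(n))
  W_list <- split.data.frame(W, mod_of)
  names(W_list) <- names(X_list)
  psi_list <- split(psi, mod_of)
  names(psi_list) <- names(X_list)
  structure(list(W = W_list, psi = psi_list, Z = EZ, d = d, C = C,
                 lambda = lambda, loglik_trace = trace, labels = labels,
                 degenerate = degenerate, seed = as.integer(seed)),
            class = "integrative_model")
}

# relabel clusters so label 1 is the largest, 2 the next, ...
relabel_by_size <- function(labels) {
  sizes <- table(labels)
  ord <- names(sizes)[order(-as.integer(sizes), names(sizes))]
  out <- match(as.character(labels), ord)
  names(out) <- names(labels)
  out
}

#' Stability report over repeated clusterings
#'
#' Pairwise adjusted Rand indices between repeats; repeats may cover
#' different sample subsets (ARI is computed on the intersection).
#'
#' @param label_list list of named label vectors.
#' @return a `stability_report`: `repeats`, `pairwise_ari` (symmetric,
#'   unit diagonal), `mean_ari`.
#' @export
stability_report <- function(label_list) {
  r <- length(label_list)
  if (r < 2) stop("stability undefined for fewer than 2 repeats")
  P <- diag(1, r)
  for (i in seq_len(r - 1)) for (j in seq.int(i + 1, r)) {
    shared <- intersect(names(label_list[[i]]), names(label_list[[j]]))
    P[i, j] <- P[j, i] <- adjusted_rand_index(label_list[[i]][shared],
                                              label_list[[j]][shared])
  }
  structure(list(repeats = r, pairwise_ari = P,
                 mean_ari = mean(P[upper.tri(P)])),
            class = "stability_report")
}

icluster_repeat_labels <- function(X_list, C, lambda, repeats, seed,
                                   subsample_frac = 0.8, max_iter = 60L) {
  n <- ncol(X_list[[1]])
  ids <- colnames(X_list[[1]]) %||% paste0("S", seq_len(n))
  seeds <- derive_seeds(seed, repeats)
  lapply(seq_len(repeats), function(r) {
    set.seed(seeds[r])
    keep <- sort(sample.int(n, max(C + 2L, round(subsample_frac * n))))
    sub <- lapply(X_list, function(m) {
      m <- m[, keep, drop = FALSE]; colnames(m) <- ids[keep]; m
    })
    fit <- icluster_fit(sub, C, lambda, seed = seeds[r],
                        max_iter = max_iter)
    structure(fit$labels, degenerate = fit$degenerate)
  })
}

#' Tune the sparsity weight on a uniform grid in `[0, 1]`
#'
#' Each candidate lambda is scored by clustering reproducibility: the
#' model is refitted `repeats` times on seeded 80% subsamples and the
#' mean pairwise adjusted Rand index of the labels is the score. The
#' best lambda maximizes the score (ties toward smaller lambda). If even
#' the best score stays below 0.5 the report flags the data as having no
#' reproducible structure.
#'
#' @param X_list list of matrices as in [icluster_fit()].
#' @param C number of clusters.
#' @param n_points grid size (default 10: `{0, 1/9, ..., 1}`).
#' @param repeats refits per candidate (>= 2).
#' @param seed base seed.
#' @return list with `best_lambda`, `grid` (data.frame lambda /
#'   mean_ari), `no_structure` flag.
#' @export
tune_lambda <- function(X_list, C, n_points = 10L, repeats = 5L,
                        seed = 1L) {
  stopifnot(n_points >= 2)
  if (repeats < 2) stop("stability undefined for repeats < 2")
  grid <- seq(0, 1, length.out = n_points)
  score <- vapply(seq_along(grid), function(i) {
    labs <- icluster_repeat_labels(X_list, C, grid[i], repeats,
                                   seed = seed + i)
    if (any(vapply(labs, function(l) isTRUE(attr(l, "degenerate")),
                   logical(1))))
      return(-Inf)                     # collapsed model: not a candidate
    stability_report(labs)$mean_ari
  }, numeric(1))
  best <- grid[order(-score, grid)][1]
  list(best_lambda = best,
       grid = data.frame(lambda = grid, mean_ari = score),
       no_structure = max(score) < 0.5)
}

#' Choose the cluster count by repeat-to-repeat stability
#'
#' For each candidate C the model is refitted `repeats` times (seeded
#' subsample refits); the C with the highest mean pairwise ARI wins,
#' ties toward smaller C.
#'
#' @param X_list list of matrices as in [icluster_fit()].
#' @param C_candidates integer candidates (default `c(3, 4)`).
#' @param repeats refits per candidate (default 20).
#' @param lambda sparsity weight used for all fits.
#' @param seed base seed.
#' @return list with `C` (chosen), `reports` (named list of
#'   [stability_report()]s), `mean_ari` per candidate.
#' @export
select_cluster_count <- function(X_list, C_candidates = c(3L, 4L),
                                 repeats = 20L, lambda = 0, seed = 1L) {
  stopifnot(length(C_candidates) >= 2)
  reports <- lapply(C_candidates, function(C) {
    labs <- icluster_repeat_labels(X_list, C, lambda, repeats,
                                   seed = seed + C)
    stability_report(labs)
  })
  names(reports) <- paste0("C", C_candidates)
  mean_ari <- vapply(reports, function(r) r$mean_ari, numeric(1))
  chosen <- C_candidates[order(-mean_ari, C_candidates)][1]
  list(C = chosen, reports = reports,
       mean_ari = setNames(mean_ari, names(reports)))
}
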