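# Consensus NMF subtyping.
#
# Brunet multiplicative updates for the KL divergence
#   D(V || WH) = sum( V * log(V / WH) - V + WH )
# with multi-run consensus clustering, cophenetic / silhouette rank
# diagnostics over k = 2..10 and a minimum-subclass-size rule.

EPS_NMF <- .Machine$double.eps

kl_divergence <- function(V, WH) {
  WH <- pmax(WH, EPS_NMF)
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

#' Fit a single NMF by KL multiplicative updates
#'
#' Random uniform initialization from `seed`; iterates the brunet update
#' rules until `max_iter` or the relative objective change drops below
#' `tol`. Rows of all zeros are removed with a warning (they carry no
#' information and break the updates).
#'
#' @param V nonnegative numeric matrix (features x samples).
#' @param k factorization rank.
#' @param seed RNG seed for the initialization.
#' @param max_iter iteration cap (default 2000).
#' @param tol relative objective-change stopping tolerance (default 1e-6).
#' @return an `nmf_fit` list: `W` (features x k), `H` (k x samples),
#'   `objective_trace` (KL per iteration, nonincreasing), `seed`.
#' @export
nmf_fit <- function(V, k, seed = 1L, max_iter = 2000L, tol = 1e-6) {
  if (!is.matrix(V) || !is.numeric(V)) stop("V must be a numeric matrix")
  if (any(V < 0)) stop("V has negative entries; NMF requires nonnegativity")
  zero_rows <- rowSums(V) == 0
  if (any(zero_rows)) {
    warning(sprintf("nmf_fit: dropping %d all-zero row(s)",
                    sum(zero_rows)))
    V <- V[!zero_rows, , drop = FALSE]
  }
  n <- nrow(V); m <- ncol(V)
  stopifnot(k >= 1, n >= k, m >= k)
  set.seed(seed)
  # init scaled to the data magnitude: makes the whole trajectory exactly
  # equivariant under V -> c*V, so labels are scale invariant
  s0 <- sqrt(mean(V) / k)
  W <- matrix(runif(n * k), n, k) * s0
  H <- matrix(runif(k * m), k, m) * s0
  trace <- numeric(0)
  obj <- kl_divergence(V, W %*% H)
  for (it in seq_len(max_iter)) {
    WH <- pmax(W %*% H, EPS_NMF)
    H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), EPS_NMF)
    WH <- pmax(W %*% H, EPS_NMF)
    W <- W * ((V / WH) %*% t(H)) / rep(pmax(rowSums(H), EPS_NMF),
                                       each = n)
    new_obj <- kl_divergence(V, W %*% H)
    trace <- c(trace, new_obj)
    if (is.finite(obj) && abs(obj - new_obj) <= tol * max(abs(obj), 1))
      { obj <- new_obj; break }
    obj <- new_obj
  }
  structure(list(W = W, H = H, objective_trace = trace,
                 seed = as.integer(seed)),
            class = "nmf_fit")
}

nmf_run_labels <- function(V, k, seed, max_iter, tol) {
  fit <- nmf_fit(V, k, seed = seed, max_iter = max_iter, tol = tol)
  apply(fit$H, 2, which.max)
}

#' Consensus clustering over repeated NMF runs
#'
#' Each run assigns every sample to the argmax row of `H`; the consensus
#' matrix holds the fraction of runs in which two samples co-cluster.
#' Final labels come from average-linkage hierarchical clustering of
#' `1 - consensus` cut at `k`; the cophenetic coefficient and the mean
#' silhouette width over consensus distances are the rank diagnostics.
#'
#' @param V nonnegative features x samples matrix with sample colnames.
#' @param k number of clusters (>= 2).
#' @param n_runs number of random restarts feeding the consensus
#'   (default 50).
#' @param seeds optional integer vector of per-run seeds
#'   (length `n_runs`); defaults to a stream derived from `seed`.
#' @param seed base seed used when `seeds` is NULL.
#' @param max_iter,tol per-run NMF stopping parameters.
#' @return a `consensus_result`: `k`, `consensus`, `cophenetic`,
#'   `mean_silhouette`, `labels` (named integer vector), `cluster_sizes`.
#' @export
consensus_cluster <- function(V, k, n_runs = 50L, seeds = NULL,
                              seed = 1L, max_iter = 2000L, tol = 1e-6) {
  stopifnot(k >= 2)
  if (n_runs < 2) stop("n_runs must be >= 2")
  seeds <- seeds %||% derive_seeds(seed, n_runs)
  stopifnot(length(seeds) == n_runs)
  m <- ncol(V)
  cons <- matrix(0, m, m)
  for (s in seeds) {
    lab <- nmf_run_labels(V, k, s, max_iter, tol)
    cons <- cons + outer(lab, lab, "==")
  }
  cons <- cons / n_runs
  dimnames(cons) <- list(colnames(V), colnames(V))
  D <- as.dist(1 - cons)
  hc <- hclust(D, method = "average")
  labels <- cutree(hc, k = k)
  coph <- suppressWarnings(cor(D, cophenetic(hc)))
  sil <- mean_silhouette(labels, 1 - cons)
  names(labels) <- colnames(V)
  structure(list(k = k, consensus = cons, cophenetic = coph,
                 mean_silhouette = sil, labels = labels,
                 cluster_sizes = as.integer(table(labels))),
            class = "consensus_result")
}

#' Select the NMF rank by consensus silhouette with a min-size rule
#'
#' Candidates whose smallest cluster falls below `min_size` are excluded;
#' among the rest the k maximizing the mean silhouette wins, ties broken
#' toward smaller k.
#'
#' @param results list of [consensus_cluster()] results (k = 2..10
#'   typically).
#' @param min_size minimum admissible subclass size (default 10).
#' @return list with `k` (chosen), `result` (the winning
#'   `consensus_result`) and `diagnostics` (one row per candidate).
#' @export
select_rank <- function(results, min_size = 10L) {
  stopifnot(length(results) >= 2)
  diag <- data.frame(
    k = vapply(results, function(r) r$k, integer(1)),
    cophenetic = vapply(results, function(r) r$cophenetic, numeric(1)),
    mean_silhouette = vapply(results, function(r) r$mean_silhouette,
                             numeric(1)),
    min_cluster = vapply(results, function(r) min(r$cluster_sizes),
                         integer(1)),
    n_clusters = vapply(results, function(r) length(r$cluster_sizes),
                        integer(1)))
  diag$admissible <- diag$min_cluster >= min_size &
    diag$n_clusters == diag$k
  if (!any(diag$admissible))
    stop("no candidate rank satisfies the minimum subclass size; ",
         "relax min_size")
  adm <- diag[diag$admissible, , drop = FALSE]
  adm <- adm[order(-adm$mean_silhouette, adm$k), , drop = FALSE]
  chosen <- adm$k[1]
  list(k = chosen,
       result = results[[which(diag$k == chosen)[1]]],
       diagnostics = diag)
}

#' One-call NMF subtyping of an expression (or CNV/MET) matrix
#'
#' Convenience wrapper: shifts a matrix containing negatives to
#' nonnegativity by its global minimum (needed for CNV input; recorded in
#' the result), runs [consensus_cluster()] over `k_min..k_max` and picks
#' the rank with [select_rank()].
#'
#' @param X numeric matrix (features x samples).
#' @param k_min,k_max candidate rank range (defaults 2, 10).
#' @param n_runs restarts per candidate (default 50).
#' @param min_size minimum subclass size (default 10).
#' @param seed base seed.
#' @param max_iter,tol per-run stopping parameters.
#' @return the [select_rank()] result plus `shift` applied and
#'   `all_results`.
#' @export
nmf_subtype <- function(X, k_min = 2L, k_max = 10L, n_runs = 50L,
                        min_size = 10L, seed = 1L, max_iter = 2000L,
                        tol = 1e-6) {
  shift <- 0
  if (any(X < 0)) {
    shift <- -min(X)
    X <- X + shift
  }
  ks <- seq.int(k_min, k_max)
  results <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    results[[i]] <- consensus_cluster(X, ks[i], n_runs = n_runs,
                                      seed = seed + ks[i],
                                      max_iter = max_iter, tol = tol)
  }
  sel <- select_rank(results, min_size = min_size)
  sel$shift <- shift
  sel$all_results <- results
  sel
}
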