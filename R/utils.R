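#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats pchisq pt qnorm dhyper fisher.test kruskal.test
#'   wilcox.test p.adjust kmeans hclust cutree cophenetic as.dist cor sd
#'   var median quantile rnorm runif rbinom rpois rnbinom rbeta rexp
#'   complete.cases setNames aggregate rmultinom prcomp
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fisher-type z transform of a correlation coefficient
#'
#' Computes `z = ln((1 + r) / (1 - r)) = 2 * atanh(r)`, the classical
#' variance-stabilizing transform up to a factor of 2. `r` is clamped to
#' `±(1 - 1e-12)` so that perfect correlations map to large finite values.
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @return numeric vector of transformed values.
#' @examples
#' fisher_z(0.5)  # log(3)
#' fisher_z(0)    # 0
#' @export
fisher_z <- function(r) {
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  log((1 + r) / (1 - r))
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' `G1 = g1 * sqrt(n (n - 1)) / (n - 2)` where `g1 = m3 / m2^(3/2)` with
#' biased central moments.
#'
#' @param x numeric vector, `length(x) >= 3` after NA removal.
#' @return the adjusted skewness (scalar).
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("skewness needs at least 3 finite values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Spearman correlation with t-approximation p-value
#'
#' Rank correlation with average ranks for ties; the two-sided p-value uses
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom, appropriate for the sample sizes this pipeline sees
#' (hundreds). Returns `NA` statistics for constant input.
#'
#' @param x,y numeric vectors of equal length; pairs with any NA dropped.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("spearman_test needs at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  rho <- max(-1, min(1, rho))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = max(p, .Machine$double.xmin), n = n)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return ARI in `[-1, 1]`; 1 for identical partitions, ~0 at chance.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Mean silhouette width of a labeling over a distance matrix.
# Hand-rolled (cluster pkg not a dependency); singleton clusters get s = 0.
mean_silhouette <- function(labels, D) {
  D <- as.matrix(D)
  n <- length(labels)
  stopifnot(nrow(D) == n)
  labs <- unique(labels)
  if (length(labs) < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(labs[labs != labels[i]],
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

# standardize matrix rows to zero mean / unit variance; constant rows -> 0
row_standardize <- function(X) {
  m <- rowMeans(X)
  s <- apply(X, 1, sd)
  s[s == 0] <- 1
  (X - m) / s
}

ow_msg <- function(...) message("[omicweave] ", sprintf(...))

# derive a stream of well-spread 31-bit seeds from one base seed
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
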