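# Per-sample aberration burdens and their pairwise correlations.
#
# Thresholds (strict inequalities, as published): a gene counts as
# Gain if CNV > 0.3, Loss if CNV < -0.3, MetHyper if beta > 0.8,
# MetHypo if beta < 0.2.

#' Burden thresholds
#' @param gain,loss,methyper,methypo cutoffs (defaults 0.3 / -0.3 /
#'   0.8 / 0.2); all comparisons strict.
#' @return named list.
#' @export
burden_thresholds <- function(gain = 0.3, loss = -0.3, methyper = 0.8,
                              methypo = 0.2) {
  list(gain = gain, loss = loss, methyper = methyper, methypo = methypo)
}

#' Count per-sample aberration burdens
#'
#' @param cnv a complete [gene_matrix()] of modality `"CNV"`.
#' @param met a complete [gene_matrix()] of modality `"MET_BETA"`
#'   (values in `[0,1]`, no NA).
#' @param thresholds a [burden_thresholds()] list.
#' @return a `burden_table` data.frame: `sample_id`, `n_gain`, `n_loss`,
#'   `n_methyper`, `n_methypo` for the samples shared by both matrices.
#' @export
compute_burdens <- function(cnv, met, thresholds = burden_thresholds()) {
  stopifnot(inherits(cnv, "gene_matrix"), modality(cnv) == "CNV",
            inherits(met, "gene_matrix"), modality(met) == "MET_BETA")
  if (anyNA(met)) stop("met matrix must be complete (post-imputation)")
  if (any(met < 0 | met > 1)) stop("MET values outside [0,1]")
  samples <- intersect(colnames(cnv), colnames(met))
  if (length(samples) == 0) stop("no shared samples")
  cm <- unclass(cnv)[, samples, drop = FALSE]
  mm <- unclass(met)[, samples, drop = FALSE]
  df <- data.frame(
    sample_id = samples,
    n_gain = colSums(cm > thresholds$gain),
    n_loss = colSums(cm < thresholds$loss),
    n_methyper = colSums(mm > thresholds$methyper),
    n_methypo = colSums(mm < thresholds$methypo),
    stringsAsFactors = FALSE)
  new_classed_df(df, "burden_table")
}

#' Pairwise correlations between burden types
#'
#' Spearman by default (`method = "pearson"` available). Constant burden
#' columns yield NA correlations for their pairs.
#'
#' @param burdens a [compute_burdens()] table (>= 3 samples).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `pairs` (data.frame of the 6 unordered pairs with
#'   rho and p) and `matrix` (full 4x4 correlation matrix).
#' @export
burden_correlations <- function(burdens, method = c("spearman",
                                                    "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(burdens, "burden_table"))
  if (nrow(burdens) < 3) stop("need >= 3 samples")
  cols <- c("n_gain", "n_loss", "n_methyper", "n_methypo")
  M <- diag(1, 4); dimnames(M) <- list(cols, cols)
  pairs <- data.frame()
  for (i in 1:3) for (j in seq.int(i + 1, 4)) {
    x <- burdens[[cols[i]]]; y <- burdens[[cols[j]]]
    if (sd(x) == 0 || sd(y) == 0) {
      rho <- NA_real_; p <- NA_real_
    } else if (method == "spearman") {
      st <- spearman_test(x, y); rho <- st$rho; p <- st$p
    } else {
      rho <- cor(x, y)
      n <- length(x)
      tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
      p <- 2 * pt(-abs(tt), df = n - 2)
    }
    M[i, j] <- M[j, i] <- rho
    pairs <- rbind(pairs, data.frame(a = cols[i], b = cols[j],
                                     rho = rho, p = p))
  }
  list(pairs = pairs, matrix = M)
}

#' Burden distributions across subtype groups
#'
#' Median/IQR per group per burden type plus a Kruskal-Wallis test
#' across groups. Groups with fewer than 2 samples are excluded with a
#' warning; with a single usable group no test is run.
#'
#' @param burdens a [compute_burdens()] table.
#' @param labels named vector (sample -> cluster label).
#' @return list with `summary` (group x burden medians and IQRs) and
#'   `tests` (burden type -> Kruskal-Wallis p, NA if untestable).
#' @export
burdens_by_group <- function(burdens, labels) {
  stopifnot(inherits(burdens, "burden_table"))
  lab <- labels[burdens$sample_id]
  if (anyNA(lab)) stop("labels do not cover all burden samples")
  sizes <- table(lab)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !(lab %in% small)
    burdens <- burdens[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  cols <- c("n_gain", "n_loss", "n_methyper", "n_methypo")
  summ <- do.call(rbind, lapply(split(seq_along(lab), lab), function(ix) {
    vals <- burdens[ix, cols, drop = FALSE]
    stats <- unlist(lapply(cols, function(cc)
      setNames(c(median(vals[[cc]]),
                 unname(diff(quantile(vals[[cc]], c(0.25, 0.75))))),
               paste0(c("median_", "iqr_"), sub("^n_", "", cc)))))
    cbind(data.frame(group = as.character(lab[ix[1]]), n = length(ix),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats)))
  }))
  rownames(summ) <- NULL
  tests <- vapply(cols, function(cc) {
    if (length(unique(lab)) < 2) return(NA_real_)
    kruskal.test(burdens[[cc]], factor(lab))$p.value
  }, numeric(1))
  list(summary = summ, tests = tests)
}
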