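# Subtype association statistics: contingency tests, per-gene mutation
# spectra, Kaplan-Meier / log-rank survival comparisons, marker-gene
# reports and a rank-based differential-expression screen.

#' Pearson chi-square test on a contingency table
#'
#' Classic Pearson statistic without continuity correction:
#' `chi2 = sum((O - E)^2 / E)` with `E` from the margins and
#' `df = (r - 1)(c - 1)`. Cells with expected counts below 5 are counted
#' and reported as a warning (the test is still returned). Row levels
#' can be dropped before testing via `drop_levels` (used, e.g., to
#' exclude an "unknown" category).
#'
#' @param observed nonnegative integer matrix (rows = feature levels,
#'   columns = groups), ideally with dimnames.
#' @param drop_levels optional character vector of row names to drop.
#' @return a `contingency_result`: `observed`, `expected`, `chi2`, `df`,
#'   `p`, `n_expected_lt5`.
#' @export
chi2_contingency <- function(observed, drop_levels = NULL) {
  observed <- as.matrix(observed)
  if (any(observed < 0) || any(observed != round(observed)))
    stop("observed must be nonnegative integers")
  if (!is.null(drop_levels)) {
    if (is.null(rownames(observed)))
      stop("drop_levels requires row names")
    missing_lv <- setdiff(drop_levels, rownames(observed))
    if (length(missing_lv))
      stop("drop_levels not found: ", paste(missing_lv, collapse = ", "))
    observed <- observed[!rownames(observed) %in% drop_levels, ,
                         drop = FALSE]
  }
  if (nrow(observed) < 2 || ncol(observed) < 2)
    stop("need at least a 2x2 table after level dropping")
  rs <- rowSums(observed); cs <- colSums(observed)
  zr <- which(rs == 0); zc <- which(cs == 0)
  if (length(zr))
    stop("zero row after dropping: ",
         rownames(observed)[zr[1]] %||% zr[1])
  if (length(zc))
    stop("zero column after dropping: ",
         colnames(observed)[zc[1]] %||% zc[1])
  n <- sum(observed)
  expected <- outer(rs, cs) / n
  chi2 <- sum((observed - expected)^2 / expected)
  df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  lt5 <- sum(expected < 5)
  if (lt5 > 0)
    warning(sprintf("%d cell(s) have expected count < 5", lt5))
  structure(list(observed = observed, expected = expected, chi2 = chi2,
                 df = df, p = pchisq(chi2, df, lower.tail = FALSE),
                 n_expected_lt5 = lt5),
            class = "contingency_result")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities not exceeding
#' that of the observed table (the classical definition, as in base R's
#' `fisher.test`, which backs this implementation); the odds ratio is
#' the conditional maximum-likelihood estimate. A table with a zero
#' margin returns `p = 1` with a `degenerate` flag.
#'
#' @param table 2x2 nonnegative integer matrix.
#' @return list with `odds_ratio`, `p`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(odds_ratio = NA_real_, p = 1, degenerate = TRUE))
  ft <- fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value,
       degenerate = FALSE)
}

#' Per-gene mutation-spectrum comparison between two sample groups
#'
#' For every mutated gene, builds the 2x2 presence/absence table
#' (mutated yes/no x group A/B), computes the Fisher exact p and
#' conditional-MLE odds ratio, applies Benjamini-Hochberg FDR across
#' genes and flags genes passing `fdr_thresh`. Genes mutated in zero
#' samples of both groups are excluded.
#'
#' @param muts a filtered [mutation_table()].
#' @param labels named vector (sample -> group label).
#' @param groupA,groupB label values (or vectors of values) defining the
#'   two groups, e.g. `groupA = 2, groupB = c(1, 3)`.
#' @param fdr_thresh significance threshold on BH FDR (default 0.001).
#' @return data.frame per gene: counts, `fisher_p`, `odds_ratio`,
#'   `fdr_bh`, `significant`; attribute `per_sample` holds per-sample
#'   nonsilent totals.
#' @export
mutation_spectrum <- function(muts, labels, groupA, groupB,
                              fdr_thresh = 0.001) {
  stopifnot(inherits(muts, "mutation_table"))
  sampleA <- names(labels)[labels %in% groupA]
  sampleB <- names(labels)[labels %in% groupB]
  if (length(sampleA) == 0 || length(sampleB) == 0)
    stop("empty group")
  keep <- muts$sample_id %in% c(sampleA, sampleB)
  m <- as.data.frame(muts)[keep, , drop = FALSE]
  genes <- sort(unique(m$gene_id))
  if (length(genes) == 0)
    stop("no mutated genes among the grouped samples")
  hitA <- tapply(m$sample_id[m$sample_id %in% sampleA],
                 m$gene_id[m$sample_id %in% sampleA],
                 function(s) length(unique(s)))
  hitB <- tapply(m$sample_id[m$sample_id %in% sampleB],
                 m$gene_id[m$sample_id %in% sampleB],
                 function(s) length(unique(s)))
  nA <- length(sampleA); nB <- length(sampleB)
  a <- ifelse(is.na(hitA[genes]), 0L, hitA[genes])
  b <- ifelse(is.na(hitB[genes]), 0L, hitB[genes])
  res <- data.frame(gene_id = genes, mut_A = as.integer(a),
                    mut_B = as.integer(b), n_A = nA, n_B = nB,
                    stringsAsFactors = FALSE)
  stats <- lapply(seq_len(nrow(res)), function(i) {
    fisher_exact_2x2(matrix(c(res$mut_A[i], nA - res$mut_A[i],
                              res$mut_B[i], nB - res$mut_B[i]), 2, 2))
  })
  res$fisher_p <- vapply(stats, `[[`, numeric(1), "p")
  res$odds_ratio <- vapply(stats, `[[`, numeric(1), "odds_ratio")
  res$fdr_bh <- p.adjust(res$fisher_p, method = "BH")
  res$significant <- res$fdr_bh < fdr_thresh
  res <- res[order(res$fisher_p), , drop = FALSE]
  rownames(res) <- NULL
  per_sample <- table(factor(m$sample_id, levels = c(sampleA, sampleB)))
  attr(res, "per_sample") <- setNames(as.integer(per_sample),
                                      names(per_sample))
  res
}

#' Kaplan-Meier curves and k-group log-rank test
#'
#' Product-limit survival estimates per group and the standard k-group
#' log-rank (score) statistic with the hypergeometric variance, df =
#' groups - 1. Requires at least one event overall; an empty group is an
#' error.
#'
#' @param times nonnegative follow-up times.
#' @param events 0/1 event indicators.
#' @param groups group labels, same length.
#' @return a `survival_comparison`: `km_curves` (list per group of
#'   data.frames time / n_risk / n_event / surv), `logrank_chi2`,
#'   `logrank_df`, `logrank_p`, `observed` and `expected` events per
#'   group.
#' @export
km_logrank <- function(times, events, groups) {
  stopifnot(length(times) == length(events),
            length(times) == length(groups))
  ok <- !(is.na(times) | is.na(events) | is.na(groups))
  times <- times[ok]; events <- events[ok]; groups <- as.character(groups[ok])
  stopifnot(all(events %in% c(0, 1)), all(times >= 0))
  glev <- sort(unique(groups))
  k <- length(glev)
  if (k < 2) stop("need >= 2 groups")
  if (any(table(factor(groups, glev)) == 0)) stop("empty group")
  if (sum(events) == 0)
    stop("no events anywhere; log-rank test undefined")
  km_curves <- lapply(glev, function(g) km_curve(times[groups == g],
                                                 events[groups == g]))
  names(km_curves) <- glev
  # log-rank over pooled event times
  etimes <- sort(unique(times[events == 1]))
  O <- setNames(numeric(k), glev)
  E <- setNames(numeric(k), glev)
  V <- matrix(0, k, k, dimnames = list(glev, glev))
  for (tt in etimes) {
    at_risk <- times >= tt
    n_t <- sum(at_risk)
    d_t <- sum(events == 1 & times == tt)
    n_g <- vapply(glev, function(g) sum(at_risk & groups == g),
                  numeric(1))
    d_g <- vapply(glev, function(g)
      sum(events == 1 & times == tt & groups == g), numeric(1))
    O <- O + d_g
    E <- E + d_t * n_g / n_t
    if (n_t > 1) {
      # hypergeometric covariance with ties
      cfac <- d_t * (n_t - d_t) / (n_t - 1)
      Vt <- cfac * (diag(n_g / n_t, k) - tcrossprod(n_g / n_t))
      V <- V + Vt
    }
  }
  idx <- seq_len(k - 1)
  u <- (O - E)[idx]
  chi2 <- tryCatch(drop(t(u) %*% solve(V[idx, idx, drop = FALSE], u)),
                   error = function(e) NA_real_)
  structure(list(km_curves = km_curves, logrank_chi2 = chi2,
                 logrank_df = k - 1,
                 logrank_p = pchisq(chi2, k - 1, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "survival_comparison")
}

# product-limit estimator for one group
km_curve <- function(times, events) {
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(tt) sum(times >= tt), numeric(1))
  n_event <- vapply(ut, function(tt) sum(times == tt & events == 1),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event, surv = surv)
}

#' Single-gene marker report
#'
#' For one gene: Spearman correlation (rho, p) of expression with its
#' promoter methylation and with its copy number, per-subtype expression
#' summaries, and a Kaplan-Meier / log-rank comparison of the high vs
#' low expression groups split at the median (ties assigned to "low":
#' high means strictly above the median).
#'
#' @param gene_id the gene to report.
#' @param expr,met,cnv [gene_matrix()] objects containing the gene.
#' @param times,events named survival vectors (sample ids as names).
#' @param labels named subtype labels.
#' @return a `marker_report` list.
#' @export
marker_analysis <- function(gene_id, expr, met, cnv, times, events,
                            labels) {
  for (nm in c("expr", "met", "cnv")) {
    m <- get(nm)
    if (!gene_id %in% rownames(m))
      stop(sprintf("gene '%s' absent from the %s matrix", gene_id, nm))
  }
  samples <- Reduce(intersect, list(colnames(expr), colnames(met),
                                    colnames(cnv), names(times)))
  if (length(samples) < 3) stop("fewer than 3 shared samples")
  e <- unclass(expr)[gene_id, samples]
  if (sd(e) == 0)
    stop("constant expression; median split impossible")
  met_cor <- spearman_test(unclass(met)[gene_id, samples], e)
  cnv_cor <- spearman_test(unclass(cnv)[gene_id, samples], e)
  lab <- labels[samples]
  by_subtype <- tapply(e, lab, function(v)
    c(n = length(v), median = median(v), mean = mean(v)))
  grp <- ifelse(e > median(e), "high", "low")
  surv <- km_logrank(times[samples], events[samples], grp)
  structure(list(gene_id = gene_id, met_vs_expr = met_cor,
                 cnv_vs_expr = cnv_cor, by_subtype = by_subtype,
                 split = grp, survival = surv),
            class = "marker_report")
}

#' Two-group differential-expression screen (rank-sum substitute)
#'
#' Per-gene two-sided Wilcoxon rank-sum test between the groups plus a
#' log2 fold change of group means with pseudocount 1; BH FDR across
#' genes. A gene passes iff `|log2FC| >= log2(fc_thresh)` and
#' `fdr < fdr_thresh`.
#'
#' @param expr a [gene_matrix()] (FPKM or counts).
#' @param labels named group labels covering the matrix samples.
#' @param groupA,groupB label values defining the two groups.
#' @param fc_thresh fold-change threshold (default 2).
#' @param fdr_thresh FDR threshold (default 0.05).
#' @return data.frame per gene: `log2fc`, `p`, `fdr`, `pass`.
#' @export
diff_expr_screen <- function(expr, labels, groupA, groupB,
                             fc_thresh = 2, fdr_thresh = 0.05) {
  stopifnot(inherits(expr, "gene_matrix"))
  sa <- intersect(colnames(expr), names(labels)[labels %in% groupA])
  sb <- intersect(colnames(expr), names(labels)[labels %in% groupB])
  if (length(sa) == 0 || length(sb) == 0) stop("empty group")
  A <- unclass(expr)[, sa, drop = FALSE]
  B <- unclass(expr)[, sb, drop = FALSE]
  p <- vapply(seq_len(nrow(A)), function(i) {
    if (sd(c(A[i, ], B[i, ])) == 0) return(1)
    suppressWarnings(wilcox.test(A[i, ], B[i, ], exact = FALSE)$p.value)
  }, numeric(1))
  log2fc <- log2((rowMeans(A) + 1) / (rowMeans(B) + 1))
  fdr <- p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(A), log2fc = log2fc, p = p, fdr = fdr,
             pass = abs(log2fc) >= log2(fc_thresh) & fdr < fdr_thresh,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Clinical-feature association tests for a subtype assignment
#'
#' Builds feature x subtype contingency tables from a clinical table
#' (stage, grade, event status, new-event type, binned age and BMI) and
#' runs [chi2_contingency()] on each.
#'
#' @param clin a [clinical_table()].
#' @param labels named subtype labels.
#' @param age_breaks,bmi_breaks bin boundaries for the continuous
#'   features.
#' @return named list of `contingency_result`s plus the tables used.
#' @export
clinical_association <- function(clin, labels,
                                 age_breaks = c(30, 50, 60, 70, 80, 90),
                                 bmi_breaks = NULL) {
  stopifnot(inherits(clin, "clinical_table"))
  lab <- labels[clin$sample_id]
  keep <- !is.na(lab)
  clin <- clin[keep, , drop = FALSE]; lab <- lab[keep]
  feats <- list(
    event = ifelse(is.na(clin$os_event), "NA",
                   ifelse(clin$os_event == 1, "Dead", "Alive")),
    stage = as.character(clin$stage),
    grade = as.character(clin$grade),
    new_event_type = as.character(clin$new_event_type),
    age = as.character(cut(clin$age, breaks = age_breaks)),
    bmi = as.character(cut(clin$bmi,
                           breaks = bmi_breaks %||%
                             quantile(clin$bmi, seq(0, 1, 0.25),
                                      na.rm = TRUE),
                           include.lowest = TRUE)))
  out <- lapply(feats, function(f) {
    tab <- table(f, lab)
    tryCatch(suppressWarnings(chi2_contingency(unclass(tab))),
             error = function(e) NULL)
  })
  out
}
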