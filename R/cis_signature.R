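# Cis-regulatory correlation screen: copy-number-driven (CNV-G) and
# methylation-driven (MET-G) gene signatures.
#
# Per gene, expression is correlated (Spearman) with the gene's own CNV
# or promoter methylation; r is mapped through the z transform
# z = ln((1+r)/(1-r)) = 2*atanh(r). Screening is two-stage: p < p_thresh
# gives the broad CNV-G / MET-G sets; the signed 95% CI of z then gives
# the sign-constrained signatures (positive for CNV, negative for MET).

#' Per-gene correlation of a molecular layer with expression
#'
#' For every gene present in both matrices, computes the Spearman
#' correlation between the layer values and expression across shared
#' samples, the transform `z = ln((1+rho)/(1-rho))`, a two-sided p-value
#' from the t approximation on `n - 2` df, and the 95% CI
#' `z ± 1.96 * 2 / sqrt(n - 3)` (scale constant 2 because the transform
#' is twice atanh). Genes with a constant vector in either matrix are
#' dropped with a logged reason.
#'
#' @param x a [gene_matrix()] of modality `"CNV"` or `"MET_BETA"`.
#' @param expr a [gene_matrix()] of modality `"EXPR_FPKM"`.
#' @return data.frame of correlation records: `gene_id`, `modality`,
#'   `rho`, `z`, `p`, `ci_low`, `ci_high`, `n`; dropped genes in
#'   `attr(, "dropped")`.
#' @export
gene_correlation <- function(x, expr) {
  stopifnot(inherits(x, "gene_matrix"), inherits(expr, "gene_matrix"))
  mod <- modality(x)
  if (!mod %in% c("CNV", "MET_BETA"))
    stop("x must be a CNV or MET_BETA matrix")
  samples <- intersect(colnames(x), colnames(expr))
  if (length(samples) < 3)
    stop("fewer than 3 shared samples between matrices")
  genes <- intersect(rownames(x), rownames(expr))
  if (length(genes) == 0) stop("no shared genes between matrices")
  xm <- unclass(x)[genes, samples, drop = FALSE]
  em <- unclass(expr)[genes, samples, drop = FALSE]
  n <- length(samples)
  # rank per row, then rowwise Pearson of the rank matrices (vectorized)
  rx <- t(apply(xm, 1, rank))
  re <- t(apply(em, 1, rank))
  rx_c <- rx - rowMeans(rx)
  re_c <- re - rowMeans(re)
  sx <- sqrt(rowSums(rx_c^2))
  se <- sqrt(rowSums(re_c^2))
  const <- sx == 0 | se == 0
  rho <- rep(NA_real_, length(genes))
  ok <- !const
  rho[ok] <- rowSums(rx_c[ok, , drop = FALSE] * re_c[ok, , drop = FALSE]) /
    (sx[ok] * se[ok])
  rho <- pmin(1, pmax(-1, rho))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1] <- .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)
  z <- fisher_z(rho)
  half <- 1.96 * 2 / sqrt(n - 3)
  rec <- data.frame(gene_id = genes, modality = mod, rho = rho, z = z,
                    p = p, ci_low = z - half, ci_high = z + half, n = n,
                    stringsAsFactors = FALSE)
  dropped <- rec$gene_id[const]
  if (length(dropped))
    ow_msg("gene_correlation: dropped %d gene(s) with constant values",
           length(dropped))
  rec <- rec[!const, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "dropped") <- dropped
  rec
}

#' Select CNV-G / MET-G signatures from correlation records
#'
#' Stage 1: genes with `p < p_thresh` form the broad sets (`cnv_g_all`,
#' `met_g_all`). Stage 2: the copy-number signature additionally requires
#' the 95% CI of z to sit above zero (`ci_low > 0`); the methylation
#' signature requires it below zero (`ci_high < 0`). Skewness of the z
#' distributions of the broad sets is the adjusted Fisher-Pearson G1.
#'
#' @param records rbind of [gene_correlation()] outputs for both
#'   modalities.
#' @param p_thresh significance threshold (default `1e-5`).
#' @return a `signature_set` list: `cnv_g_all`, `met_g_all`, `cnv_g_sig`,
#'   `met_g_sig`, `overlap`, `skewness_cnv`, `skewness_met`,
#'   `overlap_ratio_cnv`, `overlap_ratio_met`, `records`.
#' @export
select_signatures <- function(records, p_thresh = 1e-5) {
  if (is.null(records) || nrow(records) == 0)
    stop("empty correlation record list")
  cnv <- records[records$modality == "CNV", , drop = FALSE]
  met <- records[records$modality == "MET_BETA", , drop = FALSE]
  cnv_all <- cnv[cnv$p < p_thresh, , drop = FALSE]
  met_all <- met[met$p < p_thresh, , drop = FALSE]
  cnv_sig <- cnv_all$gene_id[cnv_all$ci_low > 0]
  met_sig <- met_all$gene_id[met_all$ci_high < 0]
  overlap <- intersect(cnv_sig, met_sig)
  sk <- function(z) if (length(z) >= 3) sample_skewness(z) else NA_real_
  structure(list(
    cnv_g_all = cnv_all$gene_id,
    met_g_all = met_all$gene_id,
    cnv_g_sig = cnv_sig,
    met_g_sig = met_sig,
    overlap = overlap,
    skewness_cnv = sk(cnv_all$z),
    skewness_met = sk(met_all$z),
    overlap_ratio_cnv = if (length(cnv_sig)) length(overlap) /
      length(cnv_sig) else NA_real_,
    overlap_ratio_met = if (length(met_sig)) length(overlap) /
      length(met_sig) else NA_real_,
    records = records), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf(paste0(
    "signature_set: CNV-G %d (signature %d), MET-G %d (signature %d), ",
    "overlap %d\n  skewness z(CNV) = %.3f, z(MET) = %.3f\n"),
    length(x$cnv_g_all), length(x$cnv_g_sig), length(x$met_g_all),
    length(x$met_g_sig), length(x$overlap),
    x$skewness_cnv, x$skewness_met))
  invisible(x)
}

#' Chromosome and gene-type composition of a signature
#'
#' @param genes character vector of signature gene ids (e.g.
#'   `sig$cnv_g_sig`).
#' @param ann a [gene_annotation()].
#' @return list with `by_chrom` and `by_type` count tables plus
#'   `unmapped` (genes absent from the annotation). Counts partition the
#'   mapped genes.
#' @export
summarize_signature_geography <- function(genes, ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  idx <- match(genes, ann$gene_id)
  unmapped <- genes[is.na(idx)]
  mapped <- ann[idx[!is.na(idx)], , drop = FALSE]
  list(by_chrom = table(mapped$chrom),
       by_type = table(mapped$gene_type),
       unmapped = unmapped)
}
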