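# Preprocessing: raw tables -> analysis-ready gene-level matrices.
#
# Four procedures: CNV segment merging + gene aggregation, methylation
# probe filtering + KNN imputation + promoter-window mapping, low-
# expression filtering, and silent/intronic mutation removal.

#' Preprocessing configuration
#'
#' Defaults mirror the published filters: segments with fewer than 5
#' probes dropped; 50% reciprocal overlap merges two segments; probes
#' missing in more than 70% of samples dropped; KNN imputation with
#' k = 10; promoter window 2 kb upstream to 200 bp downstream of the TSS
#' (transcription direction); genes with a zero-FPKM fraction of 0.5 or
#' more removed.
#'
#' @param min_probes minimum probe support per segment (default 5).
#' @param overlap_frac overlap fraction treated as "same interval"
#'   (default 0.5).
#' @param met_missing_frac maximum tolerated NA fraction per probe
#'   (default 0.7; removal is strictly-greater).
#' @param knn_k neighbors for beta imputation (default 10).
#' @param tss_upstream,tss_downstream promoter window in bp (defaults
#'   2000 / 200), measured in transcription direction.
#' @param expr_zero_frac genes kept iff zero-FPKM fraction `<` this
#'   (default 0.5).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(min_probes = 5L, overlap_frac = 0.5,
                              met_missing_frac = 0.7, knn_k = 10L,
                              tss_upstream = 2000L, tss_downstream = 200L,
                              expr_zero_frac = 0.5) {
  stopifnot(overlap_frac > 0, overlap_frac <= 1,
            met_missing_frac > 0, met_missing_frac <= 1,
            expr_zero_frac > 0, expr_zero_frac <= 1,
            tss_upstream > 0, tss_downstream > 0, knn_k >= 1)
  structure(list(min_probes = as.integer(min_probes),
                 overlap_frac = overlap_frac,
                 met_missing_frac = met_missing_frac,
                 knn_k = as.integer(knn_k),
                 tss_upstream = as.integer(tss_upstream),
                 tss_downstream = as.integer(tss_downstream),
                 expr_zero_frac = expr_zero_frac),
            class = "preprocess_config")
}

seg_overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

#' Merge copy-number segments within sample and chromosome
#'
#' Segments with probe support below `min_probes` are removed first.
#' Then, within each sample + chromosome, any pair of segments whose
#' overlap is at least `overlap_frac` of each segment's length
#' (reciprocal criterion; set `reciprocal = FALSE` for the
#' one-directional variant, overlap >= frac of either length) is merged
#' into the union interval. The merged value is the probe-count-weighted
#' mean of the two values (`weighted = FALSE` gives the plain mean) and
#' probe counts add. Merging repeats to a fixed point, so the operation
#' is idempotent.
#'
#' @param segs a [segment_table()].
#' @param cfg a [preprocess_config()].
#' @param reciprocal use the symmetric overlap criterion (default TRUE).
#' @param weighted probe-count-weighted merge values (default TRUE).
#' @return a merged [segment_table()].
#' @export
merge_cnv_segments <- function(segs, cfg = preprocess_config(),
                               reciprocal = TRUE, weighted = TRUE) {
  stopifnot(inherits(segs, "segment_table"))
  df <- as.data.frame(segs)
  df <- df[df$n_probes >= cfg$min_probes, , drop = FALSE]
  if (nrow(df) == 0) return(segment_table(df))
  pieces <- split(df, list(df$sample_id, df$chrom), drop = TRUE)
  merged <- lapply(pieces, merge_group, frac = cfg$overlap_frac,
                   reciprocal = reciprocal, weighted = weighted)
  out <- do.call(rbind, merged)
  out <- out[order(out$sample_id, out$chrom, out$start, out$end), ,
             drop = FALSE]
  segment_table(out)
}

merge_group <- function(g, frac, reciprocal, weighted) {
  repeat {
    g <- g[order(g$start, g$end), , drop = FALSE]
    n <- nrow(g)
    if (n < 2) return(g)
    changed <- FALSE
    i <- 1L
    while (i < nrow(g)) {
      # after sorting by start, any interval overlapping i by >= frac of
      # its own length starts before i's end; checking successive j until
      # starts pass end(i) finds all candidates
      j <- i + 1L
      while (j <= nrow(g) && g$start[j] <= g$end[i]) {
        ov <- seg_overlap_len(g$start[i], g$end[i], g$start[j], g$end[j])
        li <- g$end[i] - g$start[i] + 1L
        lj <- g$end[j] - g$start[j] + 1L
        hit <- if (reciprocal) (ov / li >= frac) && (ov / lj >= frac)
               else (ov / li >= frac) || (ov / lj >= frac)
        if (hit) {
          w <- if (weighted) c(g$n_probes[i], g$n_probes[j]) else c(1, 1)
          if (sum(w) == 0) w <- c(1, 1)
          g$value[i] <- sum(g$value[c(i, j)] * w) / sum(w)
          g$start[i] <- min(g$start[i], g$start[j])
          g$end[i] <- max(g$end[i], g$end[j])
          g$n_probes[i] <- g$n_probes[i] + g$n_probes[j]
          g <- g[-j, , drop = FALSE]
          changed <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!changed) return(g)
  }
}

#' Aggregate merged segments to a gene-level CNV matrix
#'
#' A gene's value in a sample is the unweighted mean of the values of all
#' segments overlapping the gene body by at least 1 bp; genes with no
#' covering segment get 0 (diploid baseline — absence of a segment in
#' SEG output conventionally means neutral copy number).
#'
#' @param segs a merged [segment_table()].
#' @param ann a [gene_annotation()].
#' @param samples optional sample ordering (default: sorted unique
#'   samples present in `segs`).
#' @return a [gene_matrix()] of modality `"CNV"`.
#' @export
segments_to_gene_cnv <- function(segs, ann, samples = NULL) {
  stopifnot(inherits(segs, "segment_table"),
            inherits(ann, "gene_annotation"))
  if (nrow(ann) == 0) stop("empty gene annotation")
  samples <- samples %||% sort(unique(segs$sample_id))
  genes <- ann$gene_id
  m <- matrix(0, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  if (nrow(segs) > 0) {
    sdt <- data.table::as.data.table(as.data.frame(segs))
    gdt <- data.table::data.table(gene_id = ann$gene_id, chrom = ann$chrom,
                                  start = ann$gene_start,
                                  end = ann$gene_end)
    data.table::setkey(sdt, chrom, start, end)
    ov <- data.table::foverlaps(gdt, sdt, type = "any", nomatch = NULL)
    if (nrow(ov) > 0) {
      agg <- ov[, list(value = mean(value)), by = c("gene_id", "sample_id")]
      agg <- agg[agg$sample_id %in% samples, ]
      m[cbind(match(agg$gene_id, genes), match(agg$sample_id, samples))] <-
        agg$value
    }
  }
  gene_matrix(m, "CNV")
}

#' Drop probes with excessive missingness
#'
#' A probe is retained iff its NA fraction is `<=` `met_missing_frac`
#' (removal is strictly greater — a probe missing in exactly 70% of
#' samples survives the default).
#'
#' @param beta probe x sample numeric matrix with NAs allowed.
#' @param cfg a [preprocess_config()].
#' @return the filtered matrix.
#' @export
filter_met_probes <- function(beta, cfg = preprocess_config()) {
  stopifnot(is.matrix(beta))
  frac_na <- rowMeans(is.na(beta))
  beta[frac_na <= cfg$met_missing_frac, , drop = FALSE]
}

#' KNN imputation of missing beta values
#'
#' Each NA cell is replaced by the mean of the values, at that sample, of
#' the `k` nearest probes (rows) by Euclidean distance computed over
#' mutually observed samples (normalized per shared-sample count so rows
#' with different missingness are comparable). Only rows observed at the
#' target sample are candidate neighbors. Imputed values are clipped to
#' `[0, 1]`.
#'
#' @param beta probe x sample matrix; every row needs >= 1 observed value.
#' @param k number of neighbors (default 10). If fewer candidate rows are
#'   available, all are used with a warning.
#' @return complete matrix, observed cells untouched.
#' @export
knn_impute <- function(beta, k = 10L) {
  stopifnot(is.matrix(beta))
  obs <- !is.na(beta)
  if (any(rowSums(obs) == 0))
    stop("probe(s) with all values missing: ",
         paste(head(rownames(beta)[rowSums(obs) == 0], 3),
               collapse = ", "))
  na_rows <- which(rowSums(!obs) > 0)
  if (length(na_rows) == 0) return(beta)
  out <- beta
  p <- nrow(beta)
  Xz <- beta; Xz[!obs] <- 0          # NA -> 0 lets crossprods restrict
  S2 <- Xz^2                         # to mutually observed samples
  Om <- obs * 1
  warned <- FALSE
  # squared distance over shared samples, normalized per shared count:
  # d2_ij = (sum_i x^2 + sum_j x^2 - 2 sum x_i x_j) / n_shared
  chunk <- 512L
  for (lo in seq(1L, length(na_rows), by = chunk)) {
    I <- na_rows[lo:min(lo + chunk - 1L, length(na_rows))]
    A <- tcrossprod(Xz[I, , drop = FALSE], Xz)
    N <- tcrossprod(Om[I, , drop = FALSE], Om)
    D2 <- (tcrossprod(S2[I, , drop = FALSE], Om) +
             tcrossprod(Om[I, , drop = FALSE], S2) - 2 * A) / pmax(N, 1)
    D2[N == 0] <- Inf
    for (ii in seq_along(I)) {
      i <- I[ii]
      d <- D2[ii, ]
      d[i] <- Inf
      ord <- order(d)                  # nearest rows first
      ord <- ord[is.finite(d[ord])]
      for (j in which(!obs[i, ])) {
        nb <- ord[obs[ord, j]]
        if (length(nb) == 0)
          stop("no neighbor with an observed value for ",
               rownames(beta)[i] %||% i)
        kk <- min(k, length(nb))
        if (kk < k && !warned) {
          warning(sprintf(
            "knn_impute: only %d candidate rows available (k=%d)",
            length(nb), k))
          warned <- TRUE
        }
        out[i, j] <- min(1, max(0, mean(beta[nb[seq_len(kk)], j])))
      }
    }
  }
  out
}

#' Map promoter probes to genes and average to a gene-level beta matrix
#'
#' A probe is retained for a gene iff it lies within the promoter window
#' of that gene's TSS in transcription direction: for `+` genes
#' `[tss - upstream, tss + downstream]`, for `-` genes
#' `[tss - downstream, tss + upstream]` in genomic coordinates
#' (boundaries inclusive). The gene's beta per sample is the unweighted
#' mean over its retained probes. A census of retained probes by CpG
#' region class is attached.
#'
#' @param beta imputed probe x sample matrix.
#' @param manifest a [probe_manifest()].
#' @param ann a [gene_annotation()].
#' @param cfg a [preprocess_config()].
#' @return a [gene_matrix()] of modality `"MET_BETA"` with attributes
#'   `region_census` (named counts) and `skipped_probes`.
#' @export
probes_to_gene_met <- function(beta, manifest, ann,
                               cfg = preprocess_config()) {
  stopifnot(is.matrix(beta), inherits(manifest, "probe_manifest"),
            inherits(ann, "gene_annotation"))
  man <- as.data.frame(manifest)
  man <- man[man$probe_id %in% rownames(beta), , drop = FALSE]
  skipped <- character(0)
  on_chr <- man$chrom %in% unique(ann$chrom)
  if (any(!on_chr)) {
    skipped <- man$probe_id[!on_chr]
    ow_msg("probes_to_gene_met: skipping %d probe(s) on chromosomes absent from annotation",
           length(skipped))
    man <- man[on_chr, , drop = FALSE]
  }
  # explode the gene_ids list column
  gl <- strsplit(ifelse(is.na(man$gene_ids), "", man$gene_ids), ";",
                 fixed = TRUE)
  reps <- lengths(gl)
  pairs <- data.frame(probe_id = rep(man$probe_id, reps),
                      chrom = rep(man$chrom, reps),
                      pos = rep(man$pos, reps),
                      region_class = rep(man$region_class, reps),
                      gene_id = unlist(gl), stringsAsFactors = FALSE)
  pairs <- pairs[nzchar(pairs$gene_id), , drop = FALSE]
  ai <- match(pairs$gene_id, ann$gene_id)
  pairs <- pairs[!is.na(ai), , drop = FALSE]
  ai <- ai[!is.na(ai)]
  tss <- ann$tss[ai]; strand <- ann$strand[ai]
  same_chrom <- pairs$chrom == ann$chrom[ai]
  lo <- ifelse(strand == "+", tss - cfg$tss_upstream,
               tss - cfg$tss_downstream)
  hi <- ifelse(strand == "+", tss + cfg$tss_downstream,
               tss + cfg$tss_upstream)
  keep <- same_chrom & pairs$pos >= lo & pairs$pos <= hi
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no probe falls in any promoter window")
  census <- table(factor(pairs$region_class, levels = REGION_CLASSES))
  genes <- sort(unique(pairs$gene_id))
  m <- matrix(NA_real_, length(genes), ncol(beta),
              dimnames = list(genes, colnames(beta)))
  idx <- split(seq_len(nrow(pairs)), pairs$gene_id)
  for (g in names(idx)) {
    pr <- pairs$probe_id[idx[[g]]]
    sub <- beta[pr, , drop = FALSE]
    m[g, ] <- colMeans(sub)
  }
  gm <- gene_matrix(m, "MET_BETA")
  attr(gm, "region_census") <- as.integer(census)
  names(attr(gm, "region_census")) <- names(census)
  attr(gm, "skipped_probes") <- skipped
  gm
}

#' Remove lowly expressed genes from an FPKM matrix
#'
#' A gene is retained iff the fraction of samples with FPKM exactly 0 is
#' strictly below `expr_zero_frac` (i.e. detected in more than half the
#' samples at the default).
#'
#' @param expr a [gene_matrix()] of modality `"EXPR_FPKM"`.
#' @param cfg a [preprocess_config()].
#' @return the filtered [gene_matrix()].
#' @export
filter_low_expression <- function(expr, cfg = preprocess_config()) {
  stopifnot(inherits(expr, "gene_matrix"),
            modality(expr) == "EXPR_FPKM")
  zero_frac <- rowMeans(unclass(expr) == 0)
  keep <- zero_frac < cfg$expr_zero_frac
  gene_matrix(unclass(expr)[keep, , drop = FALSE], "EXPR_FPKM")
}

#' Remove silent and intronic mutation records
#'
#' Drops every record flagged `is_silent` or `is_intronic`. Per-sample
#' silent counts from the unfiltered table are preserved in
#' `attr(result, "silent_counts")` for burden-style summaries.
#'
#' @param muts a [mutation_table()].
#' @return the filtered [mutation_table()].
#' @export
filter_mutations <- function(muts) {
  stopifnot(inherits(muts, "mutation_table"))
  silent_counts <- table(muts$sample_id[muts$is_silent])
  out <- mutation_table(as.data.frame(muts)[!(muts$is_silent |
                                                muts$is_intronic), ,
                                            drop = FALSE])
  attr(out, "silent_counts") <- setNames(as.integer(silent_counts),
                                         names(silent_counts))
  out
}
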