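# End-to-end orchestration: simulate/load -> preprocess -> signature ->
# (NMF, integrative clustering) -> burdens -> associations/survival,
# with a JSON run manifest and per-stage outputs.

#' Run configuration for the full pipeline
#'
#' @param input either a `sim_data` object (from
#'   [simulate_multiomics()]) or a named list of file paths
#'   (`segments`, `beta`, `manifest`, `fpkm`, `counts`, `mutations`,
#'   `clinical`, `annotation`) read with the omics readers.
#' @param out_dir output directory.
#' @param preprocess a [preprocess_config()].
#' @param p_thresh signature screening threshold (default 1e-5).
#' @param nmf list of NMF settings (`k_min`, `k_max`, `n_runs`,
#'   `min_size`).
#' @param icluster list of integrative-clustering settings
#'   (`C_candidates`, `repeats`, `lambda_points`).
#' @param thresholds a [burden_thresholds()].
#' @param seed integer master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(input, out_dir,
                       preprocess = preprocess_config(),
                       p_thresh = 1e-5,
                       nmf = list(k_min = 2L, k_max = 10L, n_runs = 50L,
                                  min_size = 10L),
                       icluster = list(C_candidates = c(3L, 4L),
                                       repeats = 20L,
                                       lambda_points = 10L),
                       thresholds = burden_thresholds(), seed = 1L) {
  if (is.list(input) && !inherits(input, "sim_data")) {
    missing_p <- unlist(input)[!file.exists(unlist(input))]
    if (length(missing_p))
      stop("input path(s) do not exist: ",
           paste(missing_p, collapse = ", "))
  }
  structure(list(input = input, out_dir = out_dir,
                 preprocess = preprocess, p_thresh = p_thresh,
                 nmf = nmf, icluster = icluster,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "run_config")
}

load_inputs <- function(input) {
  if (inherits(input, "sim_data")) return(input)
  list(segments = read_segments(input$segments),
       beta = read_beta_matrix(input$beta),
       manifest = read_probe_manifest(input$manifest),
       fpkm = read_gene_matrix(input$fpkm, "EXPR_FPKM"),
       counts = read_gene_matrix(input$counts, "EXPR_COUNT"),
       mutations = read_maf(input$mutations),
       clinical = read_clinical(input$clinical),
       annotation = read_annotation(input$annotation))
}

#' Run the full integrative pipeline
#'
#' Stages: preprocess (CNV merge + gene aggregation, beta filtering +
#' KNN imputation + promoter mapping, expression filter, mutation
#' filter); cis signature screen; NMF consensus subtyping on signature-
#' gene expression; integrative clustering of CNV + MET + EXP on the
#' signature genes; aberration burdens; clinical association, mutation
#' spectrum and survival comparisons for the integrative subtypes.
#' Every stage writes its tables under `out_dir/<stage>/` and the run
#' manifest records parameters, seed and wall times. Outputs are
#' deterministic under a fixed seed.
#'
#' @param cfg a [run_config()].
#' @return the manifest (invisibly also written to
#'   `out_dir/manifest.json`).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("omicweave")),
                   seed = cfg$seed, p_thresh = cfg$p_thresh,
                   thresholds = cfg$thresholds,
                   preprocess = unclass(cfg$preprocess),
                   stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }

  raw <- t_stage("load", load_inputs(cfg$input))

  pp <- t_stage("preprocess", {
    segs <- merge_cnv_segments(raw$segments, cfg$preprocess)
    cnv <- segments_to_gene_cnv(segs, raw$annotation)
    beta <- filter_met_probes(raw$beta, cfg$preprocess)
    beta <- knn_impute(beta, cfg$preprocess$knn_k)
    met <- probes_to_gene_met(beta, raw$manifest, raw$annotation,
                              cfg$preprocess)
    fpkm <- filter_low_expression(raw$fpkm, cfg$preprocess)
    muts <- filter_mutations(raw$mutations)
    write_tables(list(gene_cnv = cnv, gene_met = met,
                      fpkm_filtered = fpkm),
                 file.path(cfg$out_dir, "preprocess"), overwrite = TRUE)
    list(cnv = cnv, met = met, fpkm = fpkm, muts = muts)
  })

  sig <- t_stage("signature", {
    rec <- rbind(gene_correlation(pp$cnv, pp$fpkm),
                 gene_correlation(pp$met, pp$fpkm))
    s <- select_signatures(rec, cfg$p_thresh)
    write_tables(list(correlation_records = s$records,
                      signature_summary = list(
                        n_cnv_g = length(s$cnv_g_all),
                        n_met_g = length(s$met_g_all),
                        n_cnv_sig = length(s$cnv_g_sig),
                        n_met_sig = length(s$met_g_sig),
                        n_overlap = length(s$overlap),
                        skewness_cnv = s$skewness_cnv,
                        skewness_met = s$skewness_met)),
                 file.path(cfg$out_dir, "signature"), overwrite = TRUE)
    s
  })

  sig_genes <- union(sig$cnv_g_sig, sig$met_g_sig)
  expr_log <- log2(unclass(pp$fpkm) + 1)
  nmf_res <- t_stage("nmf", {
    X <- expr_log[intersect(sig_genes, rownames(expr_log)), ,
                  drop = FALSE]
    res <- nmf_subtype(X, k_min = cfg$nmf$k_min, k_max = cfg$nmf$k_max,
                       n_runs = cfg$nmf$n_runs,
                       min_size = cfg$nmf$min_size, seed = cfg$seed)
    write_tables(list(nmf_labels = data.frame(
      sample_id = names(res$result$labels),
      label = as.integer(res$result$labels)),
      nmf_diagnostics = res$diagnostics),
      file.path(cfg$out_dir, "nmf"), overwrite = TRUE)
    res
  })

  ic <- t_stage("icluster", {
    samples <- Reduce(intersect, list(colnames(pp$cnv), colnames(pp$met),
                                      colnames(expr_log)))
    X_list <- list(
      CNV = unclass(pp$cnv)[intersect(sig$cnv_g_sig, rownames(pp$cnv)),
                            samples, drop = FALSE],
      MET = unclass(pp$met)[intersect(sig$met_g_sig, rownames(pp$met)),
                            samples, drop = FALSE],
      EXP = expr_log[intersect(sig_genes, rownames(expr_log)), samples,
                     drop = FALSE])
    sel <- select_cluster_count(X_list,
                                C_candidates = cfg$icluster$C_candidates,
                                repeats = cfg$icluster$repeats,
                                seed = cfg$seed)
    fit <- icluster_fit(X_list, C = sel$C, lambda = 0,
                        seed = cfg$seed)
    labels <- fit$labels
    write_tables(list(icluster_labels = data.frame(
      sample_id = names(labels),
      label = paste0("iC", labels)),
      latent = fit$Z,
      stability = list(chosen_C = sel$C,
                       mean_ari = as.list(sel$mean_ari))),
      file.path(cfg$out_dir, "icluster"), overwrite = TRUE)
    list(fit = fit, labels = labels, selection = sel)
  })

  burdens <- t_stage("burden", {
    b <- compute_burdens(pp$cnv, pp$met, cfg$thresholds)
    bc <- burden_correlations(b)
    write_tables(list(burdens = b,
                      burden_correlations = bc$pairs),
                 file.path(cfg$out_dir, "burden"), overwrite = TRUE)
    b
  })

  assoc <- t_stage("association", {
    lab <- ic$labels
    clin <- raw$clinical
    ctests <- clinical_association(clin, lab)
    worst <- names(which.max(tapply(
      clin$os_event[match(names(lab), clin$sample_id)], lab, mean,
      na.rm = TRUE)))
    others <- setdiff(unique(lab), as.integer(worst))
    ms <- tryCatch(mutation_spectrum(pp$muts, lab,
                                     groupA = as.integer(worst),
                                     groupB = others),
                   error = function(e) NULL)
    idx <- match(names(lab), clin$sample_id)
    surv <- tryCatch(km_logrank(clin$os_time[idx], clin$os_event[idx],
                                paste0("iC", lab)),
                     error = function(e) NULL)
    bg <- burdens_by_group(burdens, lab)
    out <- list(association_pvalues = list(
      chi2 = lapply(ctests, function(x) if (is.null(x)) NA else x$p),
      logrank_p = if (is.null(surv)) NA else surv$logrank_p,
      burden_kruskal = as.list(bg$tests)))
    if (!is.null(ms)) out$mutation_spectrum <- ms
    write_tables(out, file.path(cfg$out_dir, "association"),
                 overwrite = TRUE)
    out
  })

  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
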