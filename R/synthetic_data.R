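# Coupled multi-omics simulator with planted structure.
#
# The generator emits exactly the raw formats the pipeline consumes —
# CNV segments, a 450k-style probe beta matrix + manifest, FPKM and
# count expression, a MAF-like mutation table, a clinical table and a
# gene annotation — under a single seed, with:
#   * planted subtype labels (one subtype carries an elevated CNV
#     aberration burden, emulating the copy-number-high class);
#   * planted cis-driven genes: expression coupled positively to copy
#     number (CNV drivers) or negatively to promoter methylation (MET
#     drivers) at a target Spearman magnitude;
#   * subtype-dependent exponential survival hazards and subtype-
#     enriched mutated genes.

GENERATOR_VERSION <- "1"

#' Simulation configuration
#'
#' Defaults describe the standard testing world used throughout the
#' package: 300 samples, 2000 genes on 5 synthetic chromosomes, 3
#' balanced subtypes, 10% CNV drivers and 10% MET drivers at target
#' correlation 0.6, subtype 2 with elevated copy-number burden and
#' hazard, 5% beta missingness.
#'
#' @param n_samples,n_genes,n_subtypes cohort dimensions
#'   (300 / 2000 / 3).
#' @param mixing subtype proportions (sum 1; default equal).
#' @param cnv_driver_frac,met_driver_frac fractions of genes that are
#'   cis-driven (0.1 each; disjoint sets).
#' @param cis_rho target correlation magnitude for drivers (0.6; values
#'   above 0.95 are rejected as infeasible).
#' @param segment_len_mean mean genes per CNV segment (20).
#' @param cnv_noise_sd per-sample segment-mean noise (0.15).
#' @param beta_noise beta-distribution concentration for probe noise
#'   (50).
#' @param hazard_ratios per-subtype hazard multipliers
#'   (`c(1, 2.5, 0.8)`; subtype 2 worst prognosis).
#' @param base_hazard baseline event rate per day (1/2000).
#' @param censor_rate independent exponential censoring rate (1/2500).
#' @param mut_rate_base background per-gene, per-sample mutation
#'   probability (0.02).
#' @param mut_enriched_n genes enriched in the designated subtype (20).
#' @param mut_enrich_odds enrichment odds for those genes (15).
#' @param mut_subtype subtype carrying the enrichment (2).
#' @param cnv_high_subtype subtype with elevated aberration burden (2).
#' @param de_frac fraction of non-driver genes with direct subtype
#'   expression shifts (0.15).
#' @param de_sd standard deviation of those shifts, log2 scale (1).
#' @param expr_sd residual expression noise, log2 scale (1).
#' @param missing_frac NA rate injected into the probe beta matrix
#'   (0.05).
#' @param dropout_rate probability an FPKM cell is zeroed (0.02).
#' @param low_gene_frac fraction of (non-driver) genes made lowly
#'   expressed to exercise the zero filter (0.05).
#' @param probes_per_gene promoter probes per gene (3).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 300L, n_genes = 2000L,
                       n_subtypes = 3L, mixing = NULL,
                       cnv_driver_frac = 0.1, met_driver_frac = 0.1,
                       cis_rho = 0.6, segment_len_mean = 20L,
                       cnv_noise_sd = 0.15, beta_noise = 50,
                       hazard_ratios = NULL, base_hazard = 1 / 2000,
                       censor_rate = 1 / 2500, mut_rate_base = 0.02,
                       mut_enriched_n = 20L, mut_enrich_odds = 15,
                       mut_subtype = 2L, cnv_high_subtype = 2L,
                       de_frac = 0.15, de_sd = 1, expr_sd = 1,
                       missing_frac = 0.05, dropout_rate = 0.02,
                       low_gene_frac = 0.05, probes_per_gene = 3L,
                       seed = 1L) {
  mixing <- mixing %||% rep(1 / n_subtypes, n_subtypes)
  hazard_ratios <- hazard_ratios %||%
    { hr <- rep(1, n_subtypes); if (n_subtypes >= 2) hr[2] <- 2.5
      if (n_subtypes >= 3) hr[3] <- 0.8; hr }
  stopifnot(length(mixing) == n_subtypes,
            abs(sum(mixing) - 1) < 1e-8,
            all(mixing >= 0), all(hazard_ratios > 0),
            cnv_driver_frac >= 0, cnv_driver_frac <= 1,
            met_driver_frac >= 0, met_driver_frac <= 1,
            missing_frac >= 0, missing_frac < 1)
  if (cis_rho > 0.95) stop("cis_rho > 0.95 is infeasible")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a coupled synthetic multi-omics dataset
#'
#' See [sim_config()] for the generative model knobs. All randomness
#' derives from `cfg$seed`; two calls with equal configs are identical.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_data` list: `segments` ([segment_table()]), `beta`
#'   (probe x sample matrix with NAs), `manifest`
#'   ([probe_manifest()]), `fpkm`, `counts` ([gene_matrix()]s),
#'   `mutations` ([mutation_table()]), `clinical`
#'   ([clinical_table()]), `annotation` ([gene_annotation()]) and
#'   `truth` (a `sim_truth` with labels, driver / enriched gene ids and
#'   the echoed config).
#' @export
simulate_multiomics <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples; G <- cfg$n_genes; K <- cfg$n_subtypes
  samples <- sprintf("S%04d", seq_len(n))
  genes <- sprintf("G%04d", seq_len(G))

  labels <- sample(seq_len(K), n, replace = TRUE, prob = cfg$mixing)
  names(labels) <- samples

  # --- genome layout: genes in order on 5 synthetic chromosomes -------
  n_chrom <- 5L
  chrom_of <- paste0("chr", ((seq_len(G) - 1L) %/% ceiling(G / n_chrom)) + 1L)
  idx_in_chrom <- as.integer(ave(seq_len(G), chrom_of, FUN = seq_along))
  gene_start <- 100001L + (idx_in_chrom - 1L) * 10000L
  gene_end <- gene_start + 1999L
  strand <- sample(c("+", "-"), G, replace = TRUE)
  gene_type <- sample(c("protein_coding", "lincRNA", "miRNA"), G,
                      replace = TRUE, prob = c(0.8, 0.15, 0.05))
  ann <- gene_annotation(data.frame(
    gene_id = genes, symbol = genes, chrom = chrom_of, strand = strand,
    gene_start = gene_start, gene_end = gene_end, gene_type = gene_type,
    stringsAsFactors = FALSE))

  # --- planted gene roles --------------------------------------------
  n_cnv_drv <- round(cfg$cnv_driver_frac * G)
  n_met_drv <- round(cfg$met_driver_frac * G)
  drv_pool <- sample(genes)
  cnv_drivers <- sort(drv_pool[seq_len(n_cnv_drv)])
  met_drivers <- sort(drv_pool[n_cnv_drv + seq_len(n_met_drv)])
  rest <- setdiff(genes, c(cnv_drivers, met_drivers))
  de_genes <- sort(sample(rest, round(cfg$de_frac * length(rest))))
  low_genes <- sort(sample(setdiff(rest, de_genes),
                           round(cfg$low_gene_frac * length(rest))))

  # --- CNV: per-subtype segment profiles -----------------------------
  seg_of <- integer(G)           # segment index per gene
  seg_id <- 0L
  for (ch in unique(chrom_of)) {
    gi <- which(chrom_of == ch)
    pos <- 1L
    while (pos <= length(gi)) {
      seg_id <- seg_id + 1L
      len <- max(1L, rpois(1, cfg$segment_len_mean))
      seg_of[gi[pos:min(pos + len - 1L, length(gi))]] <- seg_id
      pos <- pos + len
    }
  }
  n_seg <- seg_id
  p_aber <- rep(0.15, K)
  if (cfg$cnv_high_subtype <= K) p_aber[cfg$cnv_high_subtype] <- 0.4
  seg_mu <- matrix(0, n_seg, K)
  for (s in seq_len(n_seg)) for (k in seq_len(K)) {
    if (runif(1) < p_aber[k])
      seg_mu[s, k] <- sample(c(-1, 1), 1) * runif(1, 0.3, 0.7)
  }
  # per-sample segment values and the SEG table
  seg_genes <- split(seq_len(G), seg_of)
  seg_chrom <- vapply(seg_genes, function(g) chrom_of[g[1]], character(1))
  seg_start <- vapply(seg_genes, function(g) gene_start[g[1]], integer(1))
  seg_end <- vapply(seg_genes, function(g) gene_end[g[length(g)]],
                    integer(1))
  seg_nprobe <- 5L + rpois(n_seg, 3 * lengths(seg_genes))
  seg_val <- seg_mu[, labels, drop = FALSE] +
    matrix(rnorm(n_seg * n, sd = cfg$cnv_noise_sd), n_seg, n)
  segments <- segment_table(data.frame(
    sample_id = rep(samples, each = n_seg),
    chrom = rep(seg_chrom, n),
    start = rep(seg_start, n),
    end = rep(seg_end, n),
    n_probes = rep(seg_nprobe, n),
    value = as.vector(seg_val),
    stringsAsFactors = FALSE))
  cnv_gene <- seg_val[seg_of, , drop = FALSE]     # true gene-level CNV
  dimnames(cnv_gene) <- list(genes, samples)

  # --- methylation: gene-level means, then promoter probes -----------
  met_mu <- matrix(runif(G, 0.1, 0.9), G, K)      # constant across subtypes
  for (g in match(met_drivers, genes)) {
    lv <- seq(0.25, 0.75, length.out = K)
    met_mu[g, ] <- sample(lv)                     # subtype-separated means
  }
  met_gene <- met_mu[, labels, drop = FALSE] +
    matrix(rnorm(G * n, sd = 0.05), G, n)
  met_gene <- pmin(pmax(met_gene, 0.02), 0.98)
  dimnames(met_gene) <- list(genes, samples)

  ppg <- cfg$probes_per_gene
  offsets <- round(seq(-1500, 100, length.out = ppg))  # transcription dir
  probe_gene <- rep(seq_len(G), each = ppg)
  probe_off <- rep(offsets, times = G)
  probe_pos <- ifelse(strand[probe_gene] == "+",
                      gene_start[probe_gene] + probe_off,
                      gene_end[probe_gene] - probe_off)
  manifest <- probe_manifest(data.frame(
    probe_id = sprintf("cg%06d", seq_len(G * ppg)),
    chrom = chrom_of[probe_gene],
    pos = as.integer(probe_pos),
    region_class = rep(c("Island", "N_Shore", "S_Shore"),
                       length.out = G * ppg),
    gene_ids = genes[probe_gene],
    stringsAsFactors = FALSE))
  conc <- cfg$beta_noise
  mu_flat <- met_gene[probe_gene, , drop = FALSE]
  beta <- matrix(rbeta(length(mu_flat), mu_flat * conc,
                       (1 - mu_flat) * conc),
                 nrow = G * ppg, ncol = n,
                 dimnames = list(manifest$probe_id, samples))
  if (cfg$missing_frac > 0) {
    nas <- runif(length(beta)) < cfg$missing_frac
    # never blank an entire probe row
    keep_one <- cbind(seq_len(nrow(beta)),
                      sample.int(n, nrow(beta), replace = TRUE))
    nas[(keep_one[, 2] - 1L) * nrow(beta) + keep_one[, 1]] <- FALSE
    beta[nas] <- NA_real_
  }

  # --- expression ----------------------------------------------------
  base_expr <- runif(G, 2, 8)                     # log2 FPKM baseline
  L <- matrix(base_expr, G, n) +
    matrix(rnorm(G * n, sd = cfg$expr_sd), G, n)
  rho <- cfg$cis_rho
  slope <- rho / sqrt(1 - rho^2)
  ic <- match(cnv_drivers, genes)
  sd_c <- pmax(apply(cnv_gene[ic, , drop = FALSE], 1, sd), 1e-6)
  L[ic, ] <- L[ic, ] + (cfg$expr_sd * slope / sd_c) *
    (cnv_gene[ic, , drop = FALSE] - rowMeans(cnv_gene[ic, , drop = FALSE]))
  im <- match(met_drivers, genes)
  sd_m <- pmax(apply(met_gene[im, , drop = FALSE], 1, sd), 1e-6)
  L[im, ] <- L[im, ] - (cfg$expr_sd * slope / sd_m) *
    (met_gene[im, , drop = FALSE] - rowMeans(met_gene[im, , drop = FALSE]))
  ide <- match(de_genes, genes)
  de_shift <- matrix(rnorm(length(ide) * K, sd = cfg$de_sd),
                     length(ide), K)
  L[ide, ] <- L[ide, ] + de_shift[, labels, drop = FALSE]
  fpkm <- 2^L
  if (cfg$dropout_rate > 0)
    fpkm[runif(length(fpkm)) < cfg$dropout_rate] <- 0
  il <- match(low_genes, genes)
  fpkm[il, ][runif(length(il) * n) < 0.7] <- 0
  dimnames(fpkm) <- list(genes, samples)
  counts <- matrix(rnbinom(length(fpkm), mu = fpkm * 20, size = 10),
                   G, n, dimnames = dimnames(fpkm))

  # --- mutations -----------------------------------------------------
  enr_genes <- sort(sample(setdiff(genes, low_genes),
                           cfg$mut_enriched_n))
  p0 <- cfg$mut_rate_base
  p_enr <- cfg$mut_enrich_odds * p0 /
    (1 - p0 + cfg$mut_enrich_odds * p0)
  mut_bg <- matrix(runif(G * n) < p0, G, n)
  extra <- matrix(FALSE, G, n)
  enr_idx <- match(enr_genes, genes)
  in_sub <- labels == cfg$mut_subtype
  extra[enr_idx, in_sub] <-
    runif(length(enr_idx) * sum(in_sub)) < (p_enr - p0) / (1 - p0)
  classes_bg <- c("Missense_Mutation", "Nonsense_Mutation",
                  "Frame_Shift_Del", "Silent", "Intron")
  wb <- c(0.5, 0.1, 0.05, 0.22, 0.13)
  ij_bg <- which(mut_bg, arr.ind = TRUE)
  ij_ex <- which(extra & !mut_bg, arr.ind = TRUE)
  vc <- c(sample(classes_bg, nrow(ij_bg), replace = TRUE, prob = wb),
          sample(classes_bg[1:3], nrow(ij_ex), replace = TRUE,
                 prob = c(0.7, 0.2, 0.1)))
  ij <- rbind(ij_bg, ij_ex)
  mutations <- mutation_table(data.frame(
    sample_id = samples[ij[, 2]],
    gene_id = genes[ij[, 1]],
    variant_classification = vc,
    is_silent = vc == "Silent",
    is_intronic = vc == "Intron",
    stringsAsFactors = FALSE))

  # --- clinical ------------------------------------------------------
  h <- cfg$base_hazard * cfg$hazard_ratios[labels]
  t_event <- rexp(n, rate = h)
  t_cens <- rexp(n, rate = cfg$censor_rate)
  os_time <- round(pmin(t_event, t_cens)) + 1
  os_event <- as.integer(t_event <= t_cens)
  t_event2 <- rexp(n, rate = 1.5 * h)
  t_cens2 <- rexp(n, rate = cfg$censor_rate)
  pfs_time <- round(pmin(t_event2, t_cens2)) + 1
  pfs_event <- as.integer(t_event2 <= t_cens2)
  stage_probs <- matrix(rep(c(0.6, 0.1, 0.24, 0.06), K), 4, K)
  if (cfg$cnv_high_subtype <= K)
    stage_probs[, cfg$cnv_high_subtype] <- c(0.38, 0.12, 0.38, 0.12)
  stage <- vapply(labels, function(k)
    sample(c("I", "II", "III", "IV"), 1, prob = stage_probs[, k]),
    character(1))
  grade_probs <- matrix(rep(c(0.15, 0.2, 0.6, 0.05), K), 4, K)
  if (cfg$cnv_high_subtype <= K)
    grade_probs[, cfg$cnv_high_subtype] <- c(0.02, 0.08, 0.8, 0.1)
  grade <- vapply(labels, function(k)
    sample(c("G1", "G2", "G3", "G4"), 1, prob = grade_probs[, k]),
    character(1))
  age <- pmin(pmax(round(rnorm(n, 63, 10)), 31), 89)
  bmi <- round(exp(rnorm(n, log(31), 0.22)), 1)
  net <- sample(c("Primary", "Locoregional Recurrence",
                  "Distant Metastasis", "New Primary Tumor", NA),
                n, replace = TRUE,
                prob = c(0.85, 0.06, 0.04, 0.02, 0.03))
  clinical <- clinical_table(data.frame(
    sample_id = samples, os_time = os_time, os_event = os_event,
    pfs_time = pfs_time, pfs_event = pfs_event, stage = stage,
    grade = grade, age = age, bmi = bmi, new_event_type = net,
    stringsAsFactors = FALSE))

  truth <- structure(list(
    labels = labels,
    cnv_driver_ids = cnv_drivers,
    met_driver_ids = met_drivers,
    de_gene_ids = de_genes,
    low_gene_ids = low_genes,
    enriched_mutation_genes = enr_genes,
    enriched_subtype = cfg$mut_subtype,
    config = cfg,
    generator_version = GENERATOR_VERSION), class = "sim_truth")

  structure(list(segments = segments, beta = beta, manifest = manifest,
                 fpkm = gene_matrix(fpkm, "EXPR_FPKM"),
                 counts = gene_matrix(counts, "EXPR_COUNT"),
                 mutations = mutations, clinical = clinical,
                 annotation = ann, truth = truth),
            class = "sim_data")
}

#' Regenerate a dataset from its truth record
#'
#' The truth object carries the full configuration (including the seed),
#' so the original dataset can be rebuilt bit-identically.
#'
#' @param truth a `sim_truth` from [simulate_multiomics()].
#' @return the identical `sim_data` list.
#' @export
regenerate <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!identical(truth$generator_version, GENERATOR_VERSION))
    stop(sprintf("generator version mismatch: truth=%s, installed=%s",
                 truth$generator_version, GENERATOR_VERSION))
  simulate_multiomics(truth$config)
}
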