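test_that("merge_cnv_segments applies probe filter and overlap rule", {
  cfg <- preprocess_config()
  # fewer than 5 probes: removed
  low <- segment_table(data.frame(sample_id = "S1", chrom = "chr1",
                                  start = 1L, end = 100L, n_probes = 4L,
                                  value = 0.5))
  expect_equal(nrow(merge_cnv_segments(low, cfg)), 0)
  # [100,200] + [150,250]: reciprocal overlap 51/101 >= 0.5 -> merged,
  # value is the probe-weighted mean
  two <- segment_table(data.frame(
    sample_id = "S1", chrom = "chr1", start = c(100L, 150L),
    end = c(200L, 250L), n_probes = c(10L, 10L), value = c(0.2, 0.4)))
  m <- merge_cnv_segments(two, cfg)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(100L, 250L))
  expect_equal(m$value, 0.3)
  expect_equal(m$n_probes, 20L)
  # [100,200] + [190,400]: overlap 11 bp, below half -> untouched
  far <- segment_table(data.frame(
    sample_id = "S1", chrom = "chr1", start = c(100L, 190L),
    end = c(200L, 400L), n_probes = c(10L, 10L), value = c(0.2, 0.4)))
  expect_equal(nrow(merge_cnv_segments(far, cfg)), 2)
  # one-directional variant merges when one segment is engulfed
  nested <- segment_table(data.frame(
    sample_id = "S1", chrom = "chr1", start = c(100L, 120L),
    end = c(500L, 140L), n_probes = c(20L, 10L), value = c(0.1, 0.7)))
  expect_equal(nrow(merge_cnv_segments(nested, cfg)), 2)  # reciprocal: no
  expect_equal(nrow(merge_cnv_segments(nested, cfg, reciprocal = FALSE)),
               1)
})

test_that("merge_cnv_segments is idempotent and never shrinks coverage", {
  sim <- small_sim()
  set.seed(1)
  # perturb to create overlapping segments within samples
  segs <- as.data.frame(sim$segments)
  segs <- segs[segs$sample_id %in% unique(segs$sample_id)[1:5], ]
  extra <- segs
  extra$start <- pmax(1L, extra$start - 20000L)
  extra$end <- extra$end + 30000L
  both <- segment_table(rbind(segs, extra))
  m1 <- merge_cnv_segments(both)
  m2 <- merge_cnv_segments(m1)
  expect_equal(as.data.frame(m1), as.data.frame(m2))
  # coverage: union of outputs covers union of surviving inputs
  surv <- both[both$n_probes >= 5, ]
  for (s in unique(surv$sample_id)) {
    for (ch in unique(surv$chrom[surv$sample_id == s])) {
      inp <- surv[surv$sample_id == s & surv$chrom == ch, ]
      out <- m1[m1$sample_id == s & m1$chrom == ch, ]
      pts <- sort(unique(c(inp$start, inp$end)))
      covered_in <- vapply(pts, function(p)
        any(inp$start <= p & p <= inp$end), logical(1))
      covered_out <- vapply(pts, function(p)
        any(out$start <= p & p <= out$end), logical(1))
      expect_true(all(covered_out[covered_in]))
    }
  }
})

test_that("segments_to_gene_cnv averages overlapping segments", {
  ann <- tiny_annotation()
  segs <- segment_table(data.frame(
    sample_id = rep("S1", 3),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100L, 200L, 100L), end = c(180L, 300L, 2000L),
    n_probes = c(10L, 10L, 10L), value = c(0.2, 0.4, -0.7)))
  gm <- segments_to_gene_cnv(segs, ann)
  expect_equal(unname(unclass(gm)["gA", "S1"]), 0.3)   # two segments
  expect_equal(unname(unclass(gm)["gB", "S1"]), -0.7)  # engulfed
  expect_equal(unname(unclass(gm)["gC", "S1"]), 0)     # uncovered
  expect_error(segments_to_gene_cnv(segs, ann[0, ]), "empty")
})

test_that("filter_met_probes removes probes by strict missingness rule", {
  b <- matrix(NA_real_, 3, 10,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:10)))
  b[1, 1:2] <- 0.5          # 8/10 NA -> removed (0.8 > 0.7)
  b[2, 1:3] <- 0.5          # 7/10 NA -> retained (boundary)
  b[3, ] <- 0.5             # complete
  out <- filter_met_probes(b)
  expect_equal(rownames(out), c("p2", "p3"))
})

test_that("knn_impute fills NAs from nearest rows and clips", {
  # 12 rows near 0.8, one target row with NA; nearest rows all carry 0.8
  set.seed(2)
  b <- matrix(0.8, 13, 6) + matrix(rnorm(78, sd = 0.001), 13, 6)
  rownames(b) <- paste0("p", 1:13)
  b[1, 3] <- NA
  out <- knn_impute(b, k = 10)
  expect_false(anyNA(out))
  nb_vals <- b[-1, 3]
  expect_gte(out[1, 3], min(nb_vals))
  expect_lte(out[1, 3], max(nb_vals))
  # observed cells untouched
  expect_identical(out[-1, ], b[-1, ])
  expect_identical(out[1, -3], b[1, -3])
  # no NA -> identity
  expect_identical(knn_impute(b[-1, ], 5), b[-1, ])
  # k larger than candidates -> all rows used, warning
  small <- b[1:4, ]; small[1, 3] <- NA
  expect_warning(knn_impute(small, k = 10), "candidate rows")
  # all-missing probe -> error naming the probe
  dead <- b; dead[2, ] <- NA
  expect_error(knn_impute(dead), "p2")
})

test_that("knn_impute matches a brute-force oracle on a small matrix", {
  set.seed(33)
  b <- matrix(runif(20 * 8), 20, 8,
              dimnames = list(paste0("p", 1:20), paste0("s", 1:8)))
  b[cbind(c(3, 7, 12), c(2, 5, 8))] <- NA
  out <- knn_impute(b, k = 4)
  for (cell in list(c(3, 2), c(7, 5), c(12, 8))) {
    i <- cell[1]; j <- cell[2]
    d <- vapply(seq_len(nrow(b)), function(r) {
      sh <- which(!is.na(b[i, ]) & !is.na(b[r, ]))
      sqrt(mean((b[i, sh] - b[r, sh])^2))
    }, numeric(1))
    d[i] <- Inf
    cand <- setdiff(order(d), which(is.na(b[, j])))
    expect_equal(out[i, j], mean(b[cand[1:4], j]), tolerance = 1e-12)
  }
})

test_that("probes_to_gene_met applies the strand-aware promoter window", {
  ann <- gene_annotation(data.frame(
    gene_id = c("gp", "gm"), symbol = c("gp", "gm"),
    chrom = c("chr1", "chr1"), strand = c("+", "-"),
    gene_start = c(10000L, 5000L), gene_end = c(12000L, 10000L),
    gene_type = "protein_coding"))
  # '+' gene tss=10000: window [8000, 10200]
  # '-' gene tss=10000: window [9800, 12000]
  man <- probe_manifest(data.frame(
    probe_id = paste0("cg", 1:6),
    chrom = c(rep("chr1", 5), "chrX"),
    pos = c(8000L, 10200L, 10201L, 11500L, 9799L, 100L),
    region_class = c("Island", "N_Shore", "S_Shore", "Island",
                     "OpenSea", "Island"),
    gene_ids = c("gp", "gp", "gp", "gm", "gm", "gp")))
  beta <- matrix(seq(0.1, 0.6, by = 0.1), 6, 1,
                 dimnames = list(man$probe_id, "S1"))
  gm <- suppressMessages(probes_to_gene_met(beta, man, ann))
  # gp keeps cg1 (boundary inclusive) and cg2; excludes cg3
  expect_equal(unname(unclass(gm)["gp", "S1"]), mean(c(0.1, 0.2)))
  # gm keeps cg4 (1500 bp upstream in transcription direction), drops cg5
  expect_equal(unname(unclass(gm)["gm", "S1"]), 0.4)
  # chrX probe skipped (chromosome absent from annotation)
  expect_equal(attr(gm, "skipped_probes"), "cg6")
  census <- attr(gm, "region_census")
  expect_equal(sum(census), 3)
  expect_equal(unname(census["Island"]), 2L)
})

test_that("filter_low_expression drops genes by strict zero fraction", {
  m <- matrix(1, 3, 10,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:10)))
  m[1, 1:6] <- 0   # 0.6 -> removed
  m[2, 1:4] <- 0   # 0.4 -> kept
  m[3, 1:5] <- 0   # exactly 0.5 -> removed (not < 0.5)
  out <- filter_low_expression(gene_matrix(m, "EXPR_FPKM"))
  expect_equal(rownames(out), "g2")
})

test_that("filter_mutations drops silent/intronic and keeps counts", {
  muts <- mutation_table(data.frame(
    sample_id = c("S1", "S1", "S2", "S2"),
    gene_id = c("A", "B", "C", "D"),
    variant_classification = c("Missense_Mutation", "Silent", "Intron",
                               "Silent"),
    is_silent = c(FALSE, TRUE, FALSE, TRUE),
    is_intronic = c(FALSE, FALSE, TRUE, FALSE)))
  out <- filter_mutations(muts)
  expect_equal(nrow(out), 1)
  expect_equal(out$gene_id, "A")
  expect_equal(attr(out, "silent_counts"), c(S1 = 1L, S2 = 1L))
  # all-silent input
  allsil <- muts[muts$is_silent, , drop = FALSE]
  out2 <- filter_mutations(mutation_table(as.data.frame(allsil)))
  expect_equal(nrow(out2), 0)
  expect_equal(sum(attr(out2, "silent_counts")), 2)
  # empty input
  expect_equal(nrow(filter_mutations(mutation_table(
    as.data.frame(muts)[0, ]))), 0)
})
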