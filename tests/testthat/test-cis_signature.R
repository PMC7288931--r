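test_that("fisher_z is the printed closed form, odd and increasing", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), log(3))
  rh <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(fisher_z(-rh), -fisher_z(rh))        # odd
  expect_true(all(diff(fisher_z(rh)) > 0))          # strictly increasing
  expect_true(is.finite(fisher_z(1)))               # clamped
  expect_gt(fisher_z(1), 20)
})

test_that("gene_correlation produces coherent records", {
  x <- matrix(c(1, 2, 3, 4,
                4, 3, 2, 1,
                5, 5, 5, 5), 3, 4, byrow = TRUE,
              dimnames = list(c("up", "down", "flat"),
                              paste0("s", 1:4)))
  e <- matrix(c(2, 4, 6, 8,
                2, 4, 6, 8,
                1, 2, 3, 4), 3, 4, byrow = TRUE,
              dimnames = dimnames(x))
  rec <- suppressMessages(
    gene_correlation(gene_matrix(x, "CNV"),
                     gene_matrix(e, "EXPR_FPKM")))
  expect_equal(rec$rho[rec$gene_id == "up"], 1)
  expect_gt(rec$z[rec$gene_id == "up"], 20)         # clamped large
  expect_equal(rec$rho[rec$gene_id == "down"], -1)
  # constant row dropped with logged reason
  expect_false("flat" %in% rec$gene_id)
  expect_equal(attr(rec, "dropped"), "flat")
  # sign(z) = sign(rho), ci_low <= z <= ci_high
  expect_true(all(sign(rec$z) == sign(rec$rho)))
  expect_true(all(rec$ci_low <= rec$z & rec$z <= rec$ci_high))
  expect_error(
    gene_correlation(gene_matrix(x[, 1:2], "CNV"),
                     gene_matrix(e[, 1:2], "EXPR_FPKM")),
    "3 shared samples")
})

test_that("correlation p matches the t-approximation oracle and is
           monotone in |rho| at fixed n", {
  set.seed(10)
  n <- 30
  x <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
  e <- x + matrix(rnorm(5 * n, sd = 1.5), 5, n,
                  dimnames = dimnames(x))
  rec <- gene_correlation(gene_matrix(x, "CNV"),
                          gene_matrix(pmax(e - min(e), 0), "EXPR_FPKM"))
  for (i in seq_len(nrow(rec))) {
    ct <- cor.test(x[rec$gene_id[i], ], e[rec$gene_id[i], ] - min(e),
                   method = "spearman", exact = FALSE)
    expect_equal(rec$rho[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(rec$p[i], ct$p.value, tolerance = 1e-10)
  }
  ord <- order(abs(rec$rho))
  expect_true(all(diff(rec$p[ord]) <= 1e-15))
})

test_that("select_signatures applies the two-stage rule", {
  rec <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    modality = c("CNV", "CNV", "CNV", "MET_BETA", "MET_BETA"),
    rho = c(0.4, -0.4, 0.1, -0.5, -0.45),
    z = fisher_z(c(0.4, -0.4, 0.1, -0.5, -0.45)),
    p = c(1e-6, 1e-6, 0.2, 1e-7, 1e-6),
    ci_low = c(0.2, -1.2, -0.1, -1.5, -1.2),
    ci_high = c(1.2, -0.2, 0.3, -0.5, -0.4),
    n = 100, stringsAsFactors = FALSE)
  sig <- select_signatures(rec)
  expect_setequal(sig$cnv_g_all, c("a", "b"))
  expect_equal(sig$cnv_g_sig, "a")     # sign constraint bars "b"
  expect_setequal(sig$met_g_sig, c("d", "e"))
  expect_equal(sig$overlap, character(0))
  expect_error(select_signatures(rec[0, ]), "empty")
})

test_that("skewness is the adjusted Fisher-Pearson G1", {
  # symmetric sample -> 0
  expect_equal(sample_skewness(c(-2, 0, 2)), 0)
  # oracle: direct formula on a fixed sample
  x <- c(1, 2, 2, 3, 10)
  n <- 5; m <- mean(x)
  g1 <- (mean((x - m)^3)) / mean((x - m)^2)^1.5
  expect_equal(sample_skewness(x), g1 * sqrt(n * (n - 1)) / (n - 2))
})

test_that("signature geography partitions the gene set", {
  ann <- tiny_annotation()
  geo <- summarize_signature_geography(c("gA", "gB", "gC", "zz"), ann)
  expect_equal(sum(geo$by_chrom), 3)
  expect_equal(sum(geo$by_type), 3)
  expect_equal(geo$unmapped, "zz")
  geo0 <- summarize_signature_geography(character(0), ann)
  expect_equal(sum(geo0$by_chrom), 0)
})

test_that("planted cis drivers are recovered with the correct signs", {
  sim <- small_sim()
  segs <- merge_cnv_segments(sim$segments)
  cnv <- segments_to_gene_cnv(segs, sim$annotation)
  beta <- knn_impute(filter_met_probes(sim$beta), 10)
  met <- probes_to_gene_met(beta, sim$manifest, sim$annotation)
  fpkm <- filter_low_expression(sim$fpkm)
  rec <- rbind(gene_correlation(cnv, fpkm),
               gene_correlation(met, fpkm))
  sig <- select_signatures(rec)
  truth <- sim$truth
  # planted MET drivers appear in met_g_sig with negative rho only
  met_rec <- rec[rec$modality == "MET_BETA" &
                   rec$gene_id %in% sig$met_g_sig, ]
  expect_true(all(met_rec$rho < 0))
  # no planted positive-CNV driver enters the methylation signature
  expect_equal(
    intersect(truth$cnv_driver_ids, sig$met_g_sig), character(0))
  # signature containment invariants
  expect_true(all(sig$cnv_g_sig %in% sig$cnv_g_all))
  expect_true(all(sig$met_g_sig %in% sig$met_g_all))
  expect_setequal(sig$overlap, intersect(sig$cnv_g_sig, sig$met_g_sig))
})
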