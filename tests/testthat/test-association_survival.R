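test_that("chi2_contingency matches the base-R oracle and handles
           degenerate tables", {
  tab <- matrix(c(10, 20, 30, 25, 15, 5), 2, 3, byrow = TRUE)
  res <- suppressWarnings(chi2_contingency(tab))
  oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(res$chi2, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$df, unname(oracle$parameter))
  expect_equal(rowSums(res$expected), rowSums(res$observed))
  expect_equal(colSums(res$expected), colSums(res$observed))
  # perfect independence
  res0 <- chi2_contingency(matrix(10, 2, 2))
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p, 1)
  # drop_levels and zero-margin errors
  m <- matrix(c(5, 5, 0, 0, 5, 5), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "zero", "b"), NULL))
  expect_silent(chi2_contingency(m, drop_levels = "zero"))
  expect_error(chi2_contingency(m), "zero row")
  expect_error(chi2_contingency(m, drop_levels = c("zero", "a")),
               "2x2")
  expect_warning(chi2_contingency(matrix(c(2, 3, 4, 1), 2, 2)),
                 "expected count")
})

test_that("fisher_exact_2x2 equals full hypergeometric enumeration for
           all 2x2 tables with margins <= 10", {
  # frozen worked example: margins 5/5/5/5, extreme diagonal
  ex <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2))
  expect_equal(ex$p, 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2))$p, 1)
  deg <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  # sweep small tables against the enumeration oracle
  set.seed(77)
  for (i in 1:60) {
    tab <- matrix(sample(0:5, 4, replace = TRUE), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p, fisher_enum_p(tab),
                 tolerance = 1e-9,
                 label = paste(tab, collapse = ","))
  }
})

test_that("BH adjustment matches the hand-computed example and is
           monotone under p inflation", {
  p <- c(0.001, 0.02, 0.9)
  expect_equal(p.adjust(p, "BH"), c(0.003, 0.03, 0.9))
  set.seed(78)
  for (r in 1:20) {
    p1 <- runif(15)
    infl <- pmin(1, p1 + runif(15, 0, 0.2))  # enlarge every p
    q1 <- p.adjust(p1, "BH"); q2 <- p.adjust(infl, "BH")
    expect_true(all(q2 >= q1 - 1e-12))
  }
})

test_that("mutation_spectrum flags enriched genes and keeps totals", {
  muts <- mutation_table(data.frame(
    sample_id = c(paste0("A", 1:30), paste0("B", 1:5), "A1", "B2"),
    gene_id = c(rep("HOT", 30), rep("COLD", 5), "BOTH", "BOTH"),
    variant_classification = "Missense_Mutation",
    is_silent = FALSE, is_intronic = FALSE))
  labels <- setNames(rep(c("g1", "g2"), each = 50),
                     c(paste0("A", 1:50), paste0("B", 1:50)))
  res <- mutation_spectrum(muts, labels, groupA = "g1", groupB = "g2",
                           fdr_thresh = 0.001)
  hot <- res[res$gene_id == "HOT", ]
  expect_lt(hot$fisher_p, 1e-6)
  expect_true(hot$significant)
  both <- res[res$gene_id == "BOTH", ]
  expect_equal(both$fisher_p, 1)
  expect_true(all(res$fdr_bh >= res$fisher_p))
  expect_equal(sum(attr(res, "per_sample")), nrow(muts))
})

test_that("km_logrank agrees with brute-force and survival:: oracles", {
  # 6-subject toy: independent first-principles score computation
  t6 <- c(3, 5, 7, 2, 6, 9); e6 <- c(1, 0, 1, 1, 1, 0)
  g6 <- c("a", "a", "a", "b", "b", "b")
  mine <- km_logrank(t6, e6, g6)
  expect_equal(mine$logrank_chi2, logrank_oracle_2g(t6, e6, g6),
               tolerance = 1e-10)
  skip_if_not_installed("survival")
  sdf <- survival::survdiff(survival::Surv(t6, e6) ~ g6)
  expect_equal(mine$logrank_chi2, sdf$chisq, tolerance = 1e-10)
  # random 3-group datasets against survdiff, and KM against survfit
  set.seed(81)
  for (r in 1:5) {
    n <- 40
    tt <- round(rexp(n, 0.05)) + 1
    ee <- rbinom(n, 1, 0.6)
    gg <- sample(c("x", "y", "z"), n, replace = TRUE)
    if (sum(ee) == 0) next
    mine <- km_logrank(tt, ee, gg)
    sdf <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
    expect_equal(mine$logrank_chi2, sdf$chisq, tolerance = 1e-10)
    sf <- summary(survival::survfit(
      survival::Surv(tt, ee) ~ 1, subset = gg == "x"))
    km <- mine$km_curves$x
    expect_equal(km$surv[km$n_event > 0], sf$surv, tolerance = 1e-12)
  }
})

test_that("km curves are valid and contracts hold", {
  t6 <- c(3, 5, 7, 2, 6, 9); e6 <- c(1, 0, 1, 1, 1, 0)
  both <- km_logrank(c(t6, t6), c(e6, e6), rep(c("u", "v"), each = 6))
  expect_equal(both$logrank_chi2, 0, tolerance = 1e-12)
  expect_equal(both$logrank_p, 1)
  for (cv in both$km_curves) {
    expect_true(all(diff(cv$surv) <= 1e-12))   # nonincreasing
    expect_lte(cv$surv[1], 1)
  }
  expect_error(km_logrank(t6, rep(0, 6), g = rep(c("u", "v"), 3)),
               "no events")
  expect_error(km_logrank(t6, e6, rep("u", 6)), ">= 2 groups")
})

test_that("marker_analysis reports planted methylation silencing", {
  sim <- small_sim()
  segs <- merge_cnv_segments(sim$segments)
  cnv <- segments_to_gene_cnv(segs, sim$annotation)
  beta <- knn_impute(filter_met_probes(sim$beta), 10)
  met <- probes_to_gene_met(beta, sim$manifest, sim$annotation)
  fpkm <- filter_low_expression(sim$fpkm)
  clin <- sim$clinical
  times <- setNames(clin$os_time, clin$sample_id)
  events <- setNames(clin$os_event, clin$sample_id)
  gene <- intersect(sim$truth$met_driver_ids, rownames(fpkm))[1]
  rep1 <- marker_analysis(gene, fpkm, met, cnv, times, events,
                          sim$truth$labels)
  expect_lt(rep1$met_vs_expr$rho, 0)
  expect_lt(rep1$met_vs_expr$p, 0.01)
  expect_lt(abs(rep1$cnv_vs_expr$rho), 0.4)
  # ties-to-low median split: high group strictly above the median
  e <- unclass(fpkm)[gene, names(rep1$split)]
  expect_true(all(e[rep1$split == "high"] > median(e)))
  expect_error(marker_analysis("no_such_gene", fpkm, met, cnv, times,
                               events, sim$truth$labels), "absent")
  const <- gene_matrix(matrix(1, 1, ncol(fpkm),
                              dimnames = list(gene, colnames(fpkm))),
                       "EXPR_FPKM")
  expect_error(marker_analysis(gene, const, met, cnv, times, events,
                               sim$truth$labels), "constant")
})

test_that("diff_expr_screen finds planted shifts and controls nulls", {
  set.seed(83)
  n <- 50
  m <- matrix(rnbinom(200 * 2 * n, mu = 100, size = 5), 200, 2 * n)
  rownames(m) <- paste0("g", 1:200)
  colnames(m) <- paste0("s", 1:(2 * n))
  labels <- setNames(rep(c("A", "B"), each = n), colnames(m))
  # planted 4-fold gene
  m[1, labels == "A"] <- rnbinom(n, mu = 400, size = 5)
  expr <- gene_matrix(m, "EXPR_COUNT")
  res <- diff_expr_screen(expr, labels, "A", "B")
  expect_true(res$pass[res$gene_id == "g1"])
  # identical-distribution genes stay out of the pass list
  expect_lt(mean(res$pass[-1]), 0.05)
})

test_that("clinical_association reproduces subtype dependence on the
           simulated cohort", {
  # clinical draws are independent of gene count, so use a small gene
  # panel but a cohort large enough for the planted grade skew to show
  sim <- simulate_multiomics(sim_config(n_samples = 250L,
                                        n_genes = 50L, seed = 86L))
  res <- clinical_association(sim$clinical, sim$truth$labels)
  expect_true(all(c("event", "stage", "grade", "age", "bmi") %in%
                    names(res)))
  expect_s3_class(res$stage, "contingency_result")
  # grade and stage skew toward the designated subtype is detectable
  expect_lt(res$grade$p, 0.05)
  # age and bmi carry no planted association
  expect_gt(res$age$p, 0.001)
})
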