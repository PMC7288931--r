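# Shared fixtures, all built in code at test time.

# small coupled dataset reused across files (built once per test run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_multiomics(sim_config(
        n_samples = 80L, n_genes = 300L, seed = 421L,
        missing_frac = 0.03))
    cache
  }
})

tiny_segments <- function() {
  segment_table(data.frame(
    sample_id = rep("S1", 3),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100L, 150L, 500L),
    end = c(200L, 250L, 900L),
    n_probes = c(10L, 10L, 8L),
    value = c(0.2, 0.4, -0.5),
    stringsAsFactors = FALSE))
}

tiny_annotation <- function() {
  gene_annotation(data.frame(
    gene_id = c("gA", "gB", "gC"),
    symbol = c("A", "B", "C"),
    chrom = c("chr1", "chr2", "chr3"),
    strand = c("+", "-", "+"),
    gene_start = c(120L, 600L, 1000L),
    gene_end = c(260L, 800L, 1500L),
    gene_type = c("protein_coding", "protein_coding", "lincRNA"),
    stringsAsFactors = FALSE))
}

write_tsv_fixture <- function(df, name = "fixture.tsv") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  path
}

# independent oracle: two-sided Fisher exact p by full enumeration of
# tables with the observed margins
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  amin <- max(0, k - n2); amax <- min(m, k)
  probs <- dhyper(amin:amax, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent oracle: 2-group log-rank score statistic computed from
# first principles (hypergeometric moments at each distinct event time)
logrank_oracle_2g <- function(time, event, group) {
  glev <- sort(unique(group))
  stopifnot(length(glev) == 2)
  u <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at <- time >= tt
    n <- sum(at); n1 <- sum(at & group == glev[1])
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & group == glev[1])
    u <- u + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (u^2) / v
}
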