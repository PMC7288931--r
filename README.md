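# omicweave

Integrative genomic–epigenetic subtyping of tumor multi-omics data, as a
tested, reusable R pipeline.

## The problem

Endometrial carcinoma (and many other tumors) carries two partly
independent layers of regulatory aberration: DNA copy-number variation
(CNV) and promoter DNA methylation. Genes whose expression tracks their
own copy number (*CNV-driven*, expression–CNV correlation positive) or
their own promoter methylation (*methylation-driven*, correlation
negative) define gene signatures that, in turn, stratify patients into
molecular subtypes with different survival, mutation spectra and
clinical features. `omicweave` implements that whole analysis for anyone
with gene-level (or raw segment/probe-level) CNV, methylation-β and
expression matrices — plus a coupled multi-omics simulator with planted
truth, so every stage is testable without any external download.

## What it computes

- **Preprocessing** — SEG-style segment merging (segments with < 5
  probes removed; ≥ 50% reciprocal overlap merged), segment→gene
  aggregation (overlapping segment values averaged; uncovered genes = 0
  = diploid), 450k-style probe filtering (NA in > 70% of samples
  removed), KNN imputation (k = 10, Euclidean over mutually observed
  samples), strand-aware promoter mapping (TSS −2 kb … +200 bp in
  transcription direction), zero-FPKM expression filtering, and
  silent/intronic mutation removal.
- **Cis-regulatory screen** — per gene, Spearman ρ of the layer against
  expression; z = ln((1+ρ)/(1−ρ)) = 2·atanh(ρ); two-sided p from the t
  approximation on n−2 df. Broad sets at p < 10⁻⁵; signatures
  additionally require the 95% CI of z to be all-positive (CNV) or
  all-negative (MET).
- **NMF consensus subtyping** — from-scratch multiplicative updates for
  the Kullback–Leibler divergence ("brunet"), 50-restart consensus
  matrices for k = 2…10, cophenetic and silhouette diagnostics, minimum
  subclass size 10.
- **Joint latent-variable integrative clustering** — Gaussian model
  X_t = W_t Z + ε_t per modality with latent dimension d = C−1, fitted
  by EM with an exact per-feature lasso M-step (penalized likelihood
  ascends monotonically); cluster labels via k-means on E[Z]; λ tuned
  on 10 grid points in [0,1]; C chosen by 20-repeat stability (mean
  pairwise adjusted Rand index).
- **Aberration burdens** — per-sample counts of Gain (CNV > 0.3), Loss
  (CNV < −0.3), MetHyper (β > 0.8), MetHypo (β < 0.2), their pairwise
  Spearman correlations, and Kruskal–Wallis comparisons across
  subtypes.
- **Associations & survival** — Pearson chi-square contingency tests
  for clinical features, per-gene Fisher-exact mutation spectra with
  Benjamini–Hochberg FDR, hand-rolled Kaplan–Meier / k-group log-rank
  (verified against `survival::survdiff` to 1e-10), median-split marker
  reports, and a rank-sum differential-expression screen (|log2FC| ≥ 1,
  FDR < 0.05).

## Worked example

```r
library(omicweave)

# a coupled synthetic cohort: 120 samples, 500 genes, 3 subtypes,
# planted cis-driven genes at Spearman rho ~ 0.6
sim  <- simulate_multiomics(sim_config(n_samples = 120, n_genes = 500,
                                       seed = 1))
segs <- merge_cnv_segments(sim$segments)
cnv  <- segments_to_gene_cnv(segs, sim$annotation)
beta <- knn_impute(filter_met_probes(sim$beta), k = 10)
met  <- probes_to_gene_met(beta, sim$manifest, sim$annotation)
fpkm <- filter_low_expression(sim$fpkm)

rec <- rbind(gene_correlation(cnv, fpkm), gene_correlation(met, fpkm))
sig <- select_signatures(rec, p_thresh = 1e-5)
print(sig)
#> signature_set: CNV-G 68 (signature 59), MET-G 50 (signature 50), overlap 7
#>   skewness z(CNV) = -2.028, z(MET) = -0.080

mean(sim$truth$cnv_driver_ids %in% sig$cnv_g_sig)   # planted-driver recall
#> [1] 0.96
```

Here `CNV-G 68` is the number of genes whose copy number correlates
with their expression at p < 10⁻⁵; `signature 59` of them also have a
strictly positive 95% CI for z, the sign-constrained copy-number
signature. The recall line checks the screen against the simulator's
planted truth. The full pipeline (subtyping, burdens, survival) runs as
one call via `run_all(run_config(sim, "out/"))`, or from the shell via
the installed `exec/omicweave` CLI (`simulate`, `run-all`).

The package also bundles the clinical-feature contingency tables of the
reference 421-sample endometrial-carcinoma cohort:

```r
ev <- chi2_contingency(ec_clinical_tables()$event)
sprintf("chi2 = %.2f, df = %d, p = %.5f", ev$chi2, ev$df, ev$p)
#> "chi2 = 19.09, df = 4, p = 0.00076"
```

## Repository layout

`R/` implementation (one file per pipeline stage) · `tests/testthat/`
unit, property and acceptance suites (fixtures are generated in code)
· `vignettes/omicweave-methods.Rmd` the methods notes · `scripts/`
the acceptance report.
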