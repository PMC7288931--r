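---
title: "omicweave: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{omicweave: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical models behind each stage of the
pipeline, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the design decisions taken
where the published procedure left the details open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Preprocessing

**Segment merging.** Copy-number input is a SEG-style table of
per-sample segments (1-based closed coordinates, log2-ratio-like
segment means). Segments supported by fewer than `min_probes = 5`
probes are removed. Within each sample and chromosome, two segments
whose overlap is at least `overlap_frac = 0.5` of *each* segment's
length are treated as the same interval and merged into their union;
merging repeats until no pair qualifies, which makes the operation
idempotent. Two open choices and how we fixed them:

* *Reciprocal vs one-directional overlap.* "50% overlap" can mean 50%
  of either interval or of both. We default to the reciprocal
  criterion because it is symmetric and therefore independent of the
  order in which segments are visited; `reciprocal = FALSE` gives the
  one-directional variant (a small engulfed segment then merges into a
  large one).
* *Merged value.* The merged segment mean is the probe-count-weighted
  mean of the two inputs (`weighted = FALSE` for the plain mean).
  Probe counts measure how much evidence each segment carries; the
  unweighted mean is kept for the gene-aggregation step below, where
  the published rule says plainly "averaged".

**Segment → gene.** A gene's CNV value in a sample is the unweighted
mean of all merged segments overlapping the gene body by ≥ 1 bp. Genes
with no covering segment get **0**, not `NA`: absence of a segment in
SEG output conventionally means neutral copy number, and a numeric
baseline lets the downstream correlation screen use every sample.

**Methylation.** Probes missing in *more than* 70% of samples are
removed (a probe missing in exactly 70% survives; the removal rule is
strictly greater). Remaining NAs are KNN-imputed: for each missing
cell, the k = 10 nearest probes (rows) by Euclidean distance over
mutually observed samples — normalized by the number of shared samples
so rows with different missingness are comparable — that are observed
at the target sample contribute their mean. Imputed values are clipped
to [0, 1]. k = 10 mirrors the de-facto standard of array imputation;
the published procedure names the algorithm but not k. Probes are then
assigned to genes when they fall in the promoter window **TSS − 2 kb to
TSS + 200 bp in transcription direction** (for `-` genes the window is
[tss − 200, tss + 2000] in genomic coordinates; boundaries inclusive),
and a gene's β is the unweighted mean of its retained probes.

**Expression.** A gene is kept iff its fraction of zero-FPKM samples is
strictly below 0.5. The published sentence inverts this ("accounting
for < 0.5 … were removed"); we adopt the evident intent — keep genes
detected in at least half the cohort — since the literal reading would
discard exactly the well-measured genes.

**Mutations.** Records classified `Silent` or `Intron` are dropped
(the mapping from variant classification is configurable); per-sample
silent counts are retained alongside for burden-style summaries.

## 2. Cis-regulatory screen

For each gene, Spearman's ρ between its CNV (or promoter β) and its
expression across shared samples, with average ranks for ties. The
transform is

$$z = \ln\frac{1+\rho}{1-\rho} = 2\,\mathrm{atanh}(\rho),$$

i.e. the classical variance-stabilizing transform up to a factor of 2,
with ρ clamped to ±(1 − 10⁻¹²). The 95% CI is z ± 1.96 · 2/√(n−3) —
the scale constant 2 makes the CI exact for this transform. The
two-sided p comes from the t approximation t = ρ√((n−2)/(1−ρ²)) on
n − 2 df, adequate for cohorts of hundreds (an exact test would only
matter below n ≈ 10). Because p is computed from ρ directly, signature
membership does not depend on the factor-of-2 convention.

Selection is two-stage: genes with p < 10⁻⁵ form the broad CNV-G /
MET-G sets; the *signatures* additionally require the CI of z to sit
strictly above zero (CNV; positively driven) or strictly below (MET;
negatively driven). The two-stage reading is one consistent
interpretation of a published procedure that names both the p threshold
and a "95% confidence interval" criterion without spelling out their
composition. Overlap ratios are reported as overlap/signature-size for
each signature, the only denominator consistent with the published
percentages. Skewness of the z distributions is the adjusted
Fisher–Pearson statistic G1 = g1·√(n(n−1))/(n−2).

## 3. NMF consensus subtyping

`nmf_fit()` implements the multiplicative updates for the KL objective
D(V‖WH) (the "brunet" variant), random-uniform initialization scaled
to √(mean(V)/k) — which makes the entire trajectory exactly
equivariant under V → cV, so labels are scale invariant — iteration
cap 2000 and relative tolerance 10⁻⁶. The published "50 iterations" is
read as 50 random restarts feeding a consensus matrix (the `nrun`
semantics of the NMF ecosystem): 50 gradient iterations would be far
from convergence, while 50 restarts is the standard consensus recipe.
Per run, samples are assigned to the argmax row of H; the consensus
entry (i, j) is the co-assignment fraction; final labels cut an
average-linkage tree of 1 − consensus at k. Rank selection over
k = 2…10 excludes candidates whose smallest cluster is below 10 and
maximizes the mean silhouette width of the consensus ("average profile
width"), ties toward smaller k; the cophenetic coefficient is reported
alongside. CNV matrices (which contain losses < 0) are shifted by
their global minimum before factorization — NMF requires
nonnegativity and the shift is recorded in the result. Clustering
defaults to the expression of the signature genes; the raw CNV/MET
values are available behind a flag.

## 4. Joint latent-variable integrative clustering

Per modality t, the Gaussian model X_t = W_t Z + ε_t with Z ∼ N(0, I_d)
shared across modalities, diagonal noise Ψ_t, and latent dimension
**d = C − 1** for C clusters (the convention that reconciles "K = 2
(class 3)" phrasing). Features are row-standardized first — modalities
live on incommensurate scales. The fit is EM:

* E-step: E[Z|X] = (I + WᵀΨ⁻¹W)⁻¹WᵀΨ⁻¹X, with the matching second
  moment.
* M-step: each feature's loading row solves an exact d-dimensional
  lasso (coordinate descent, threshold λ·n·ψᵢ on the n-scaled
  objective), then Ψ in closed form. Because both conditional updates
  maximize the penalized minorant, the observed penalized
  log-likelihood per sample (computed by the Woodbury identity and
  monitored every iteration) is nondecreasing — asserted in the tests.

Initialization is from the top-d SVD of the stacked standardized data
plus a small seeded jitter; the jitter is what makes independently
seeded refits genuinely independent. Labels come from k-means on the
columns of E[Z] (20 restarts, seeded), with clusters renamed in
decreasing size order (iC1 = largest). A fit whose latent columns
collapse to fewer than C distinct points (e.g. full shrinkage at
λ = 1) is flagged degenerate and yields a single trivial cluster
rather than an error.

λ is tuned on the uniform grid {0, 1/9, …, 1}. Each candidate is
scored by *reproducibility*: the model is refitted on seeded 80%
subsamples and the mean pairwise adjusted Rand index of the labels is
the score; degenerate fits disqualify a candidate. C ∈ {3, 4} is
chosen the same way with 20 repeats, ties toward smaller C. "More
stable clustering" is operationalized as mean pairwise ARI; a best
score below 0.5 flags the data as having no reproducible structure
(unstructured data rarely exceeds ~0.4 under subsampled refits, while
planted structure approaches 1 — the tests demonstrate both regimes).

## 5. Aberration burdens

Per sample, counts of genes with CNV > 0.3 (Gain), CNV < −0.3 (Loss),
β > 0.8 (MetHyper), β < 0.2 (MetHypo) — strict inequalities exactly as
published, over the full post-preprocessing gene sets (the published
counts are per-sample totals, not signature-restricted). Pairwise
burden correlations default to Spearman for consistency with the rest
of the pipeline (Pearson behind a flag; the source does not name the
statistic). Group comparisons use Kruskal–Wallis.

## 6. Associations and survival

The contingency test is the Pearson chi-square without continuity
correction, df = (r−1)(c−1); cells with expected counts below 5 are
counted into a warning. The bundled cohort tables reproduce the
published p-values only under specific level handling, pinned in the
tests: the vital-status table *includes* its NA row as a category
(3×3, df = 4), while the recurrence-type table *excludes* its unknown
("Un") row (4×3, df = 6); both dialects are reachable through
`drop_levels`.

The Fisher exact test (2×2, two-sided by summing hypergeometric
probabilities ≤ the observed table's, conditional-MLE odds ratio) backs
the per-gene mutation spectrum, with Benjamini–Hochberg FDR across
genes; the default significance threshold is FDR < 0.001 (the stricter
of the two published thresholds; both are configurable). Kaplan–Meier
curves are the product-limit estimator; the k-group log-rank statistic
uses the hypergeometric variance with ties, df = k − 1, and is verified
in the tests against both a first-principles 2-group oracle and
`survival::survdiff` to 10⁻¹⁰. Marker reports split samples at the
median expression with ties assigned to "low" (the published analysis
does not state the tie rule), and the univariate survival analysis is
log-rank on that split (Cox regression would be the natural
alternative; it is out of scope). The differential-expression screen
substitutes a two-sided rank-sum test with |log2FC| ≥ 1 (pseudocount
1) and FDR < 0.05 for a negative-binomial model, deliberately: the
thresholds are the published ones, the test is distribution-free.

## 7. The synthetic world

`simulate_multiomics()` emits every raw format the pipeline reads,
all from one seed. The stated world (the defaults):

* 300 samples, 2000 genes on 5 synthetic chromosomes (genes every
  10 kb, 2 kb long, random strand), 3 balanced subtypes;
* CNV segments of ~20 consecutive genes; per subtype a segment is
  aberrant with probability 0.15 (mean shift ±U(0.3, 0.7)), raised to
  0.4 in subtype 2 — the copy-number-high class; per-sample noise
  SD 0.15;
* 10% CNV drivers and 10% MET drivers (disjoint): expression gains a
  term a·CNV (or −b·β) with the coefficient set from the realized
  layer SD to target Spearman ≈ 0.6 through the relation
  a = σₑ/σ_c · ρ/√(1−ρ²); MET-driver promoter means separate by
  subtype across {0.25, 0.5, 0.75}; probe-level β is
  Beta-distributed around the gene mean (concentration 50), 3 probes
  per promoter, region classes cycling Island / N_Shore / S_Shore,
  5% missingness;
* 15% of remaining genes carry direct subtype expression shifts
  (SD 1 on log2 scale); 5% are made lowly expressed to exercise the
  zero filter; counts are negative binomial (dispersion 0.1) around
  20× FPKM;
* survival is exponential with per-subtype hazard ratios (1, 2.5,
  0.8) on a 1/2000-per-day baseline and independent exponential
  censoring (1/2500) — the simplest model producing clearly separated
  survival curves with a realistic (~60–70%) censoring fraction;
* mutations are per-gene-per-sample Bernoulli (rate 0.02) with 20
  genes enriched in subtype 2 at odds 15; stage and grade
  distributions skew toward subtype 2.

What the generator does **not** emulate: linkage between neighboring
genes' expression, realistic genome coordinates and gene lengths,
allele-specific copy number, batch effects, and the long-tailed
mutation-rate heterogeneity of real tumors. A green recovery test
therefore establishes that the pipeline detects the planted effect
sizes at the planted sample sizes under well-behaved noise — not that
it would match any particular cohort's headline gene counts, which
depend on the real data's correlation structure.

## 8. Numerical choices and degenerate inputs

* NMF updates guard denominators and the KL log with machine epsilon;
  the objective is asserted nonincreasing to 10⁻⁸ slack.
* The EM noise variances are floored at 10⁻⁶ (zero-noise data would
  otherwise make the likelihood unbounded); likelihood ascent is
  asserted to 10⁻⁶ relative slack.
* Spearman p-values are floored at the smallest positive double;
  constant vectors are dropped from the correlation screen with a
  logged reason, error out in marker analysis (no median split
  exists), and yield NA correlations in the burden matrix.
* Parsers never silently drop rows; skips are logged and counted.
* All multi-run procedures draw per-run seeds from one base seed via
  a seeded `sample.int` stream, keeping every derived seed below
  2³¹.

## 9. Known limitations

Single shared λ across modalities (per-modality λ behind a flag is
future work); no Cox models; no GSEA/pathway layer; TIMER-style immune
deconvolution is consumed as precomputed score columns, never
estimated; DESeq2-class count models are intentionally substituted by
the rank-sum screen. The consensus-NMF stage is O(runs × iterations ×
features × samples) and dominates pipeline runtime; the defaults are
sized for cohorts of a few hundred samples.
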