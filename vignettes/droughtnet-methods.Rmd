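---
title: "Methods: consensus hormone co-expression networks under drought"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus hormone co-expression networks under drought}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtnet)
```

## The analysis

droughtnet reconstructs, as a tested pipeline, a cross-variety analysis of
hormone signaling under long-term drought. The study design it targets is
two plant varieties observed at five time points (days 0, 2, 5, 15, 30)
under a watered control and a drought treatment, with three replicates per
cell; day 0 is sampled once per variety and serves as the shared
pre-treatment baseline of both groups. Inputs are gene-by-sample abundance
matrices on the FPKM scale, replicate-level measurements of six hormones
(ZR, IAA, GA3, ABA, BR, JA-me; ng per g fresh weight), a table mapping
genes to hormone-signaling pathways and protein families (PP2C, ABF,
SnRK2, ...), and a cross-variety homolog map.

The pipeline stages are:

1. **Differential expression** (`test_stage()`, `call_degs()`). At every
   treated day, drought vs control replicates are compared per gene with
   Welch's two-sample t-test on log2(FPKM + 1); p-values are
   Benjamini--Hochberg adjusted across the genes of that stage, and a gene
   is a DEG iff its FPKM-scale fold change is at least 2 (|log2FC| >= 1)
   *and* its FDR is below 0.01. Day 0 is never tested. The original study
   used DESeq2 on counts; a count model is deliberately out of scope here,
   and the Welch test is an injection point a user can swap.
2. **Consensus correlation networks** (`build_network()`). Per variety and
   condition, the node set is the union over stages of called DEGs that
   are annotated to a hormone pathway, plus all six hormones. Every
   unordered node pair is evaluated by Pearson and Spearman correlation;
   an edge requires |coefficient| > 0.7 and p < 0.05 under *both* methods
   (strict inequalities, raw p-values — no multiplicity correction, as an
   explicit fidelity choice with an optional BH switch).
3. **Differential and common networks** (`differential_edges()`,
   `common_network()`). Edges are classified gained/lost/stable between
   conditions within a variety. Gene-level drought edges are collapsed to
   protein-family level (mean Pearson coefficient per sign; a family pair
   with both signs becomes one *mixed* edge carrying both component
   means), and a family-pair edge enters the common network only when both
   varieties contribute a qualifying drought edge for that pair. When one
   variety contributes a sign the other lacks, that variety's label is
   attached — the K/B annotation style of the source figure.
4. **Hubs** (`degree_centrality()`). Degree is the count of distinct
   neighbours (mixed edges count once); all maximal-degree nodes are
   flagged pivotal, with ties sharing rank 1.
5. **Group comparisons** (`duncan_mrt()`, `group_compare_table()`).
   Duncan's multiple range test with compact letter displays for hormone
   and phenotype tables.

## Statistical choices worth knowing

**Correlation p-values.** Pearson p-values use the exact t transform
t = r sqrt((n-2)/(1-r^2)). Spearman p-values apply the *same* t
approximation to rho, rather than the exact permutation distribution or
the AS89 approximation, so that both methods are treated uniformly at the
small sample sizes in play (n = 12--15). This is approximate and
documented as such; at n = 5 the implied significance boundary is
|r| = 0.878, and the test suite checks that no weaker correlation is ever
significant at that n.

**Which samples are correlated.** Correlations use all replicate-level
samples of one variety and condition across days (a `--per-stage-means`
switch offers day means instead, since the source is silent on this
point). The drought sample set contains the treated samples only (n = 12)
while the control set includes the shared day-0 baseline (n = 15,
"up to 15"). Folding day 0 into the drought set would be statistically
corrosive: every drought-responsive gene then shares the baseline-vs-
induced mean pattern, and any two induced DEGs would correlate at
|r| ~ 0.95 through that pattern alone, regardless of their co-regulation.
Excluding the baseline makes drought-network edges reflect co-variation
*within* the treated condition.

**Z-scores.** `zscore_rows()` (the display transform) standardizes
log2(FPKM + 1) rows with the sample (n - 1) standard deviation; constant
rows map to zeros. The convention is declared here because both
conventions appear in the wild; the worked example in the tests
([0, 3] -> ±0.7071) pins it.

**Duncan's test.** Critical ranges use studentized-range quantiles from
`stats::qtukey` (numerical inversion, no hard-coded tables) at Duncan's
protection level alpha_p = 1 - (1 - alpha)^(p-1), with the harmonic mean
group size for unbalanced designs. The step-down rule is strict: a span
declared homogeneous shields all its internal pairs from ever being
declared different, and letters come from the maximal homogeneous
intervals. Because alpha_p >= alpha, Duncan separates every pair Tukey's
HSD separates — a property the suite verifies on random data.

## The synthetic world

`simulate_study()` emulates the design so the full pipeline can run and be
validated with no external data. Its choices:

- **Noise model.** Abundances are log-normal: log2(FPKM + 1) is a
  per-gene baseline (uniform on [2, 8] log2 units) plus iid Gaussian
  replicate noise with sd `dispersion`. The pipeline consumes FPKM, so no
  count model is simulated (a stated non-goal).
- **Dispersion default 0.15** (~11% CV). Each emulated replicate pools six
  plants, so low replicate-level variance is plausible; more importantly,
  the defaults are chosen for *testability*: Welch's test at n = 3 has as
  few as 2 degrees of freedom, and at sd 0.25 even an 8-fold effect
  misses FDR < 0.01 in roughly a quarter of stages — no correct caller
  could meet the recovery criteria there. At 0.15 per-stage power is
  ~97%, so recovery failures indicate implementation bugs, which is what
  the tests are for.
- **Planted DEGs.** A `deg_fraction` of genes receives a signed constant
  `deg_log2fc` shift (default 3, i.e. 8-fold) in all treated drought
  samples.
- **Planted hub module.** The hub gene and its signed partners all load,
  with coefficient ±1, a shared *deterministic* stress trajectory: a
  centred log(day) ramp over the treated days scaled to variance tau^2,
  with tau chosen so that the population correlation between any two
  module members across drought samples is exactly
  `planted_r` = tau^2/(tau^2 + dispersion^2). Replicates at the same day
  share the trajectory value, so within-day variance — and hence DEG
  power — is untouched. Making the trajectory deterministic rather than a
  day-level random effect keeps the calibration exact in every run; the
  run-to-run stochasticity is the replicate noise. Module genes also
  carry the constant DEG shift, and their baselines are drawn from
  [6.5, 9] log2 units so down-swings never clip at the FPKM floor (which
  would flatten the planted correlation). Control samples carry no
  trajectory: module pairs are null under control.
- **A geometric fact about the module.** With hub--partner correlation
  0.95 and k >= 6 partners, positive semidefiniteness forces every
  partner--partner correlation above (0.95^2 k - 1)/(k - 1) ~ 0.88. The
  planted star is therefore *necessarily* observed as a near-clique, all
  of whose nodes tie on degree. Two consequences, honestly stated: the
  recoverable hub property is that the hub *attains* maximal degree
  (rank 1, possibly tied), and within-module pairs are excluded from
  false-positive accounting (they are consensus edges by geometry, not
  errors).
- **Hormones.** Only ABA and IAA respond to drought, accumulating
  progressively: their log2 effects are affine in the same centred
  log-day coordinate (slope 0.55), anchored so the ABA ratio at day 2 and
  the IAA ratio at day 5 equal `aba_effect` (3) and `iaa_effect` (2.5)
  exactly. Setting both ratios to 1 yields the fully null world used for
  calibration tests. An optional `couple_aba` flag adds the module
  trajectory to ABA, planting an ABA--hub correlation.
- **One gene universe.** Both varieties share gene IDs (the homolog map is
  the identity); variety-specific genomes exist only in the real study.

What a green test establishes, and what it does not: the suite
demonstrates correct arithmetic (against independent oracles), correct
thresholds, calibrated null behaviour, and recovery of planted structure
under the stated noise model. It does not demonstrate robustness to count
noise, normalization artefacts, unbalanced designs, or stage-specific
regulation — the generator plants stage-constant effects, and its
stage-specific DEG patterns arise from noise only.

## The deterministic topology fixture

`fig4_fixture()` is a fully deterministic two-variety dataset whose
pipeline output reproduces the published qualitative topology: a PP2C
family hub with strictly maximal degree, positive edges to ABF, SnRK2 and
GID, negative edges to A-ARR and BZR, and a mixed-sign IAA edge whose
minority (negative) component comes from variety BX alone. It is built by
*exact* sample-correlation engineering: seeded normals are column-centred,
orthonormalized (QR) and coloured by the Cholesky factor of a target
correlation matrix, so drought-sample Pearson correlations are exact by
construction — hub--partner pairs at 0.99 x 0.82 = 0.8118 (pass) and
partner--partner pairs at 0.82^2 = 0.6724 (fail, below 0.7). Spearman
statistics of such data remain stochastic, so the fixture's hard-coded
seed was validated once so that every hub-pair Spearman also clears 0.7
and no stray edge reaches the common network; the fixture is a constructed
object, and that validation is part of its construction. Control samples
use an exactly-identity correlation target. Running the fixture twice
yields byte-identical files.

## Numerical and degenerate-input conventions

- Zero-variance genes in both groups are untestable: p = 1, never a DEG.
- Constant nodes are dropped from networks with a warning; zero-variance
  correlation pairs are excluded with a warning rather than NaN.
- |r| = 1 maps to p = 0 exactly.
- An all-constant ANOVA (no within-group variance) is an input error, as
  is a Duncan call with mse = 0.
- Homolog maps resolve many-to-many relations greedily by descending
  similarity, ties broken lexicographically by partner ID.
- BH adjustment is order-preserving and capped at 1.
- All stochastic operations derive their RNG streams from the single
  config seed and restore the caller's RNG state.

## Known limitations

- The Welch-on-FPKM test is a declared stand-in for a count model; its
  power profile differs from DESeq2's, especially for low-abundance genes.
- Spearman p-values are approximate at small n (by design, documented).
- The common network matches varieties at the protein-family level, not
  via gene-level homology; the homolog map is used only for common-DEG
  counting.
- The generator cannot express stage-specific regulation programs or
  hub-specific (non-clique) correlation at planted_r close to 1 — the
  latter is mathematically impossible, not an implementation limit.
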