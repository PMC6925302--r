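---
title: "Methods: cross-study concordance of CRISPR dependency screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-study concordance of CRISPR dependency screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenconcord)
```

## The problem

Genome-scale CRISPR-Cas9 dropout screens estimate, for every gene in every
cell line, how much cell viability drops when the gene is knocked out.
When two institutes screen the same cell-line panel with different sgRNA
libraries, assay lengths, media and analysis pipelines, the question is
whether they agree — on which genes are essential everywhere, on which
genes are selectively essential in particular lines, on which molecular
features predict those selective dependencies, and on whether a cell
line's genome-wide dependency profile is even recognizable across
studies. `screenconcord` implements that comparison as a reusable,
testable pipeline, together with a synthetic two-study screen generator
with known ground truth so every stage can be verified without any
external download.

## From read counts to gene scores

Raw data are sgRNA-by-sample read counts plus plasmid-DNA (pDNA) reference
samples. The scoring chain is:

1. **RPM + pseudocount.** Each sample is scaled to reads per million and a
   pseudocount of 1 is added afterwards (`counts_to_rpm()`), so log ratios
   are always defined. The pseudocount is applied to the RPM, not to the
   raw counts.
2. **Log fold change versus pDNA.** Within each pDNA batch the available
   pDNA RPM profiles are median-collapsed into a single reference, and
   every screen sample is compared to the reference of its own batch:
   `FC = log2(sample) - log2(reference)` (`log_fold_change()`).
3. **Guide collapse.** Per replicate, a gene's score is the median of its
   targeting guides (`collapse_guides()`; the mean is used instead when
   preparing input for batch correction).
4. **Reference anchoring.** Each replicate column is shifted and scaled so
   the median of a prior nonessential gene set is exactly 0 and the median
   of a prior essential set exactly −1 (`scale_to_reference()`). These two
   anchors give scores a portable unit: −1 means "as depleted as a typical
   essential gene". A global single-factor mode (divide by −median of
   essentials) is provided for externally processed matrices that must not
   be re-centered per line.
5. **Replicate collapse.** Replicates are median-collapsed to a
   gene-by-cell-line matrix (`collapse_replicates()`).

With deterministic counts, perfect guides and no batch terms this chain
reproduces the generator's true gene effects exactly (to machine
precision) when the pseudocount is set to 0; at finite sequencing depth
the pseudocount compresses extreme depletions slightly, which is why the
exact-identity check is run in that mode.

## Batch correction

Cross-study correction follows a fixed four-step order: mean-collapse
guide fold changes to gene-by-line matrices, quantile normalize each study
separately, adjust with single-batch-factor ComBat (batch = study), then
quantile normalize the corrected joint matrix (`correct_pipeline()`).

The ComBat step (`combat_correct()`) is the parametric empirical-Bayes
location/scale adjustment: genes are standardized against their pooled
mean and variance, per-batch per-gene location (γ) and scale (δ) effects
are estimated, shrunk toward method-of-moments hyperpriors (normal for γ,
inverse-gamma for δ) by a fixed-point iteration, and the data
back-transformed. Numerical choices:

* The fixed-point iteration stops when the relative change of the EB
  estimates falls below `conv = 1e-4` (capped at 100 iterations), the
  standard stopping rule for this procedure; with it the adjustment
  matches the reference Bioconductor implementation to ~1e−15, which the
  test suite verifies on a 50 × 20 fixture.
* Genes with zero variance inside any batch cannot be standardized; they
  are passed through unadjusted and flagged in an attribute rather than
  silently altered.
* Shrinkage means a finite-noise additive batch shift is *almost*, not
  exactly, removed: the retained fraction is ≈ δ²/(n·τ² + δ²) per gene.
  Only in the limit where within-batch noise vanishes (prior variance
  dominates) does removal become exact, and that limit is what the
  exact-removal test exercises (within-batch jitter SD 1e−5).

## Common essentials: 90th-percentile ranking and density minimum

For each gene we find its 90th-percentile least-depleted cell line (linear
interpolation over its scores, then the line nearest that value, ties
resolved toward the less depleted line) and record the gene's depletion
rank among all genes in that line, normalized to (0, 1]
(`ninetieth_percentile_rankings()`). Genes essential in virtually every
line still rank near the top in their 90th-percentile line, so the
distribution of these rankings is bimodal; the threshold is the central
minimum of a Gaussian kernel density (width 0.1, 512-point grid on
[0, 1]) between the two outermost density maxima
(`density_minimum_threshold()`). A unimodal density is an error rather
than a silent guess — the caller has no natural threshold there.
Normalizing rankings to [0, 1] is what makes the fixed kernel width
meaningful across gene universes of different sizes.

## Dependency binarization at 5% FDR

Two complementary rules are implemented:

* **Global empirical null** (`global_fdr_binarize()`): nonessential-gene
  scores across all lines (and both studies, when a joint matrix is
  given) form the null; each score gets the smoothed left-tail p-value
  `p = (#null ≤ x + 1)/(N + 1)` (the +1 avoids zero p-values), BH
  correction runs across all scores, and the largest score at FDR ≤ 5%
  becomes the binarization threshold.
* **Per-line rank/precision rule** (`per_line_rank_fdr()`): genes are
  ranked by depletion; walking down the list, the precision PPV(k) among
  reference essentials/nonessentials is tracked; k\* is the largest rank
  with PPV ≥ 0.95, F\* the score at that rank, and genes strictly below
  F\* are called. Rank ties break on gene name so calls are
  deterministic. Per-line screen quality (TPR) is the recall of the
  common-essential set under this rule (`screen_quality_tpr()`).

## NormLRT selectivity and SSDs

A strongly selective dependency (SSD) has a score profile that is
near-zero in most lines with a heavy negative tail in a dependent
minority — poorly described by a Gaussian, well described by a skew-t. The
selectivity score is `LRT = 2(ll_skewt − ll_gauss)` where both terms are
maximized log-likelihoods for the gene's profile (`normlrt_scores()`).
The skew-t density is the Azzalini (ξ, ω, α, ν) form, written directly on
top of the central-t kernels; fitting details:

* Quasi-Newton (L-BFGS-B) on (ξ, log ω, α, log ν) from a
  method-of-moments start and, in parallel, from the Gaussian-limit point
  (α = 0, large ν); the better optimum is kept. If both fail, the staged
  fallback refits with ν held at each of (2, 5, 10, 25, 50, 100, 250,
  500, 1000) and then releases all four parameters; genes where every
  attempt fails carry a blank LRT.
* ν is optimized on the log scale and bounded to [1, 1e6]. The upper
  bound is deliberately far above the fallback list: the Gaussian is the
  α → 0, ν → ∞ limit of the skew-t, and a tight ν cap (say 1000) leaves
  the nested Gaussian just out of reach, producing spuriously negative
  LRT values of order 0.01–0.05 on perfectly Gaussian profiles. With the
  wide bound the nesting property holds to the documented tolerance
  (LRT ≥ −1e−3).
* Calibration at the panel size used throughout (147 lines): Gaussian
  profiles essentially never exceed LRT 100, while minority-dependent
  profiles (10% of lines at −2, noise 0.2) exceed it with ≥ 90%
  frequency. The LRT is invariant under common affine rescaling of a
  profile.

Genes with LRT > 100 and mean score > −0.5 (so common essentials are
excluded) in at least one study are classified as SSDs
(`classify_ssd()`).

## Agreement metrics

* Score level: overall Pearson/Spearman over all (gene, line) pairs,
  per-gene correlations, correlation of gene means
  (`correlation_suite()`).
* Call level: Cohen's kappa (overall and per gene), two-sided Fisher
  exact test, precision/recall with one study as reference, and AUROC of
  one study's continuous scores against the other's binary calls,
  computed by the midrank Mann-Whitney identity so ties are exact
  (`binarized_agreement()`); per-line Jaccard agreement of called gene
  sets (`per_line_jaccard()`, with J ≡ 1 flagged when both sets are
  empty).
* Profile level: every cell line appears once per study; for each of the
  2n profiles all others are ranked by correlation distance (1 − Pearson,
  ties broken by profile name) and the rank of the cross-study
  counterpart recorded. recall(k) is the percentage of profiles whose
  counterpart sits within their k nearest neighbors; nAUC is the mean
  recall over k, scaled to [0, 1] (`knn_recall_nauc()`). This definition
  yields 1 for perfect matching and ≈ 0.5 when counterpart structure is
  destroyed, which pins down the normalization unambiguously.
* Quality versus agreement: OLS of per-line agreement on mean per-line
  TPR, with the slope t-test and adjusted R² (`quality_vs_agreement()`).

## Biomarkers

Binary molecular features (mutations, copy-number events, tissue, MSI)
are filtered to a prevalence window (≥ 3 positive lines and fewer than
`n_lines − 3` by default, mirroring the ≥3 / <144-of-147 window at the
reference panel size). Each (feature, SSD gene) pair is tested with an
unpaired equal-variance Student's t-test, BH-corrected, with effect size
Cohen's delta = (mean difference)/(pooled SD); the significance rule is
FDR < 5% together with ΔFC < −1 (`differential_dependency()`).
Expression–dependency mining correlates expression profiles with SSD
dependency profiles, maps r to a t statistic with n − 2 degrees of
freedom, and corrects with Storey q-values (λ grid 0.05–0.95, df-3
spline; the spline-based π₀ estimate needs a reasonably large p-value
ensemble, so below 100 tests π₀ is held at 1, making q-values coincide
with BH there). Cross-study recovery treats the top 20/40/60/80/100% most
significant FDR < 5% associations of one study as positives and scores a
rank classifier built from the other study's p-values
(`cross_study_recovery()`).

## Batch-effect decomposition

`pca_screens()` runs centered PCA over screens (screens as observations);
`loading_enrichment()` tests gene sets for over-representation among the
extreme loadings of a component (top 5% per tail by default — the tail
fraction is a parameter because no canonical cutoff exists for
loading-sorted enrichment; the hypergeometric tail is used as the
over-representation test). `cotargeting_correlations()` compares within-
and between-study correlations of guides targeting the same gene;
`mese()` gives each gene's median estimated guide efficacy per library,
and `efficacy_difference_filter()` removes study-exclusive genes whose
efficacy difference is > 2 null SDs so enrichment of exclusive
dependencies (`exclusive_dependency_enrichment()`) reflects biology
rather than reagents. `early_late_resampling_test()` compares a gene
set's median study-mean score difference against size-matched random
draws (10,000 by default) and reports both the empirical p and a
Gaussian-tail extrapolation from the null mean/SD — the extrapolation is
what makes p-values below 1/n_perm quotable; it is two-sided by default
with a one-sided option. `condition_difference_analysis()` forms
per-gene difference profiles between screens differing in exactly one
condition (library, time point, clone, site), their correlation matrix,
and — relative to a reference screen — the variance of the difference and
its correlation with the mean inter-study difference profile, which is
the detrending evidence that matching library and time point removes most
of the batch effect.

## The synthetic generator

`simulate_pair()` emulates the experimental contrast between the two
compared pipelines: two libraries with different per-guide efficacies (4
vs 5 guides per gene, Beta(8,2) vs Beta(7,2) efficacy draws), a 14-day
versus a 21-day readout, shared common essentials, and per-gene batch
distortions on top of shared biology. The generative model per guide g
(gene j, line l, study s) is

```
FC = efficacy_g * effect_s[j, l] * (1 + scale_j * [s = B]) + shift_j * [s = B]
```

plus per-screen Gaussian noise, with counts drawn negative-binomially
around pDNA abundance × 2^FC. Default conditions (chosen once, as the
regime the compared studies operate in, and stated here rather than in
any test):

* 147 cell lines — the shared panel size of the compared studies; the
  NormLRT cut of 100 is only meaningful near this n, since the statistic
  scales with the number of lines. 600 genes — a scaled-down universe
  that keeps the full suite fast; class proportions (15% common
  essential, 30 late essentials, 10 SSDs) approximate real panels, where
  essentials are a minority. Test fixtures use 150–300 genes and 25–40
  lines where the property under test does not depend on panel size.
* Essential effect −1 (the anchoring unit); late essentials at −0.5 with
  −0.4 extra at the 21-day readout; SSD effect −2 in biomarker-positive
  lines. SSD biomarkers are minority events (3 lines up to 20% of the
  panel): a 50/50 bimodal profile is symmetric, and a skew-t cannot
  prefer it over a Gaussian, so balanced "selectivity" is undetectable by
  NormLRT by construction. Decoy features (no effect) span the full 3 to
  50% prevalence window.
* Shared per-gene-per-line biological variability SD 0.1 — the signal
  that makes a line's profile recognizable across studies; additive
  per-gene batch shift SD 0.1 and multiplicative SD 0.05 applied to study
  B — consistent with replication experiments in which the total per-gene
  inter-study difference (including library and time-point effects,
  modeled separately here) has SD ≈ 0.16–0.22; per-screen noise SD drawn
  uniformly from [0.1, 0.3] (screen quality varies by line); NB
  dispersion 0.1; 500k reads per sample; 2 replicates; 2 pDNA profiles
  per library.
* `count_model = "expected"` emits deterministic expected counts for
  exact-identity checks; `"poisson"` covers the zero-dispersion case.

What the generator does **not** emulate: copy-number-driven cutting
artifacts (the reason CERES/CRISPRcleanR exist — their outputs are
accepted as externally processed inputs instead), PCR chimeras,
cell-cycle effects, guide off-target activity, and media-composition
dependencies. Passing tests on this generator therefore demonstrate that
the statistical machinery recovers planted structure under realistic
noise, library and time-point contrasts — not that any particular real
data set is artifact-free.

## Degenerate inputs and tie-breaks (summary)

Zero-variance profiles: Gaussian fit fails, LRT blank. Constant
predictors: regression and correlation report errors or NA rather than
fabricating values. Equal essential/nonessential medians: scaling refuses
(degenerate unit). Empty joint call sets: Jaccard defined as 1 and
flagged. Ranking and neighbor ties: broken by gene/profile name, so every
result is reproducible run to run. All simulation randomness flows from a
single integer seed.

## Problem sizes used by the checks

The test suite and the acceptance script run the default 600-gene ×
147-line pair (one full pipeline ≈ 45 s, dominated by ~1,200 skew-t
fits), five 300-gene × 40-line pairs for the correction-benefit
replicates, five default-size pairs for truth recovery, 2,000 Gaussian
profiles plus 100 planted SSD profiles at n = 147 for NormLRT
calibration/power, and 200 resampling replicates for null calibration.
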