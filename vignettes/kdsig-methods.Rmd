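---
title: "Models and methods behind kdsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kdsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdsig)
```

`kdsig` packages the computational core of a knock-down-signature study of
SWI/SNF composition in prostate cancer: deriving a SMARCA4 depletion
signature from a cell-line RNA-seq experiment, scoring clinical cohorts
with it, testing phenotype associations, and quantifying the protein
interactome of the complex by co-immunoprecipitation mass spectrometry.
This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## The signature model

A knock-down signature treats an siRNA depletion experiment as the
*definition* of a transcriptional state. The derivation chain is:

1. **Low-expression filter.** A gene is kept only if its log2-CPM
   (pseudo-count 1, raw library sizes) reaches 1 in all but at most three
   samples (`min_logcpm = 1`, `max_fail_samples = 3`). The boundary is
   inclusive — failing in exactly three samples keeps the gene. Whether
   the three-sample allowance should scale with cohort size is an open
   question for very large designs; here it is an absolute, configurable
   parameter, appropriate for the 6–12-sample experiments it is meant for.
2. **TMM normalization** (`tmm_factors()`). Between-sample scaling factors
   from the weighted trimmed mean of M-values: reference sample chosen by
   upper-quartile count fraction closest to the mean, two-sided trims of
   0.30 on M and 0.05 on A, inverse asymptotic-binomial-variance weights,
   factors rescaled to geometric mean one. The computation is delegated to
   edgeR, the reference implementation of this algorithm; the test suite
   cross-checks it against an independent longhand implementation of the
   published formula to 1e-10.
3. **Moderated t statistics** (`moderated_t_test()`). A per-gene linear
   model on log2-CPM with the group contrast and, when supplied, a batch
   factor in the design matrix. Residual variances are shrunk toward a
   pooled prior by empirical Bayes (limma's `lmFit`/`eBayes`), which adds
   prior degrees of freedom and stabilizes small-replicate experiments. The
   same engine tests protein intensities in the co-IP arm, so RNA and
   protein results share one definition of effect size, p-value and FDR.
   With a single feature there is nothing to shrink and the statistic
   reduces exactly to the ordinary two-sample t. The count model this
   replaces in the original analysis chain was a negative-binomial
   quasi-likelihood F-test; the moderated t on TMM log2-CPM is a documented
   stand-in that preserves what the signature derivation actually consumes
   — a ranking by fold change and FDR — and the substitution is recorded in
   every signature file's metadata.
4. **Thresholds and ranking** (`derive_signature()`). Genes with
   |log2FC| ≥ 1.5 and FDR < 0.01 are ranked by FDR, then |log2FC|, then
   gene id (a deterministic tie-break), and truncated to the top 419. The
   1.5 threshold is interpreted on the log2 scale; reading it instead as a
   plain fold change of 1.5 (|log2FC| ≥ 0.585) is a one-parameter change,
   and the choice used is stored in the signature metadata. How the
   original 419 genes were ranked is not recoverable from the published
   description, so the ranking rule above is this package's own, fixed and
   documented.

**Scoring** (`score_cohort()`): gene expression is z-scored *within the
cohort being scored*, not against the derivation experiment — scores are
comparable within a cohort only, which is how they are used (quartile
classes, per-cohort tests). The raw score is the weight-weighted sum of
z-scores; the default weights are fold-change signs, with the fold changes
themselves available via `weight_mode = "log2fc"` ("weighted sum" admits
both readings; sign weighting is the minimal one and both are recorded).
Raw scores are affinely rescaled so the empirical 2.5%/97.5% quantiles
(type-7 interpolation) equal −1/+1, and the bottom and top ⌊n/4⌋ samples
form the *low* and *high* classes, ties at a boundary broken by sample id.
Zero-variance or absent signature genes are skipped with a message.

## Association statistics

These are implemented from first principles because their exactness is
load-bearing for small cohort tables, and each exact path is verified
against brute-force enumeration in the tests:

- `fisher_exact_2x2()`: two-sided p as the sum of hypergeometric
  probabilities not exceeding the observed table's (relative slack 1e-7
  for floating-point ties — the dominant convention, and the one that
  reproduces the published cohort-table p-values of 1.77e-05 and 0.011
  from the printed counts). The reported estimate is the sample odds ratio.
  The mid-quartile samples are dropped, not pooled, when forming
  extreme-quartile tables; that choice reproduces the printed table sizes
  (n = 138 and n = 25).
- `mann_whitney_u()`: exact by enumeration of labelings when the combined
  sample is at most 12 without ties, otherwise normal approximation with
  midranks, tie-corrected variance and continuity correction.
- `mann_kendall()`: S from concordant-minus-discordant pairs. For series
  of up to 8 values the p-value is computed from the full permutation null
  of the observed values; at such lengths the textbook normal
  approximation (tie-corrected variance, ±1 continuity correction) is off
  by up to ~0.01, which is material when the test is applied to ten score
  deciles. Longer series use the normal approximation.
- `two_proportion_test()`: pooled-variance score test, z² identical to the
  Pearson chi-square; Yates-style continuity correction behind a flag,
  off by default since the published analysis does not state the variant.
- `km_logrank()`: product-limit curves and the 1-df log-rank chi-square
  from observed-vs-expected events over pooled risk sets. Multivariable
  proportional-hazards modelling is deliberately out of scope; the
  headline survival contrast is the log-rank test.

`associate_scores()` wires a scored cohort to the battery: extreme-quartile
Fisher (CRPC-NE vs CRPC-Adeno), Mann–Whitney across the extreme Gleason
grade groups, Mann–Kendall on the percentage of high-risk samples
(risk score > 0.7) across score deciles, and, when follow-up columns are
present, low-vs-high log-rank.

## Co-IP mass spectrometry

Label-free pulldowns are compared against an IgG isotype control.
`top3_quantify()` rolls peptides up to proteins as the sum of the three
most intense observed peptides per condition/replicate (with an evidence
count when fewer than three are observed; a protein is missing in a
replicate only when nothing was observed). Peptide "variance
stabilization" in the source platform is not specified beyond the phrase;
`normalize_peptides()` implements it as log2 transformation plus exact
median alignment across samples — deterministic, testable, and standard
for this data type — with an inverse-hyperbolic-sine variant behind a flag
for data containing zeros. The normalization name travels with the output.

**Imputation** (`impute_missing()`) follows the left-censored
missing-not-at-random model: intensities drop out because they are low, so
missing cells are drawn from a Gaussian centered *below* the observed
distribution of the same sample — mean_s − downshift·sd_s with width
width·sd_s, per sample (column), not globally. Width and downshift are
multiples of the per-sample SD, the only scale on which the canonical
parameter values are meaningful: (0.3, 1.8) at peptide level and
(0.2, 2.5) at protein level. A feature qualifies only if some condition
has at least two observed values; unqualified features are dropped and
reported. Draws are seeded, and enrichment results on fully observed data
are independent of the imputation seed.

`enrichment_test()` reuses the moderated-t engine on log2 intensities (IP
minus IgG) with BH adjustment. `significance_curve()` then applies the
volcano criterion: significant iff |log2FC| > 1 and
−log10(p_adj) ≥ −log10(0.05) + c/(|log2FC| − 1), with c one times the
overall SD of the fold changes. This hyperbolic form is the conventional
reading of a "curve parameter" criterion — the admissible adjusted p is
0.05 at large fold change and tightens to zero as |log2FC| approaches 1 —
and it is isolated in one function so an alternative form can be swapped
in. Whether the original volcano used LFQ or Top3 intensities is not
stated; both paths are supported (LFQ roll-up itself belongs to the
upstream search platform and is accepted as input, Top3 is computed
natively), and `compare_enrichment()` joins two experiments' results into
the 2D fold-change table used for cross-cell-line comparison.

**Dimethyl ratios** (`dimethyl_ratios()`): PSMs need heavy+light S/N ≥ 10,
proteins need ≥ 8 surviving PSMs, the ratio is log2 of total experimental
S/N over total control S/N, and a zero control total — the theoretical
ideal for a bait-specific partner — is replaced by a denominator of one.

## Synthetic data: what it emulates, and what it does not

No noise model for the clinical cohorts is published, so all generator
parameters are explicit configuration with defaults chosen once as
realistic for this field:

- `simulate_kd_counts()`: NB counts, variance μ + φμ², default dispersion
  0.1 (typical for cell-line RNA-seq), baseline log2 mean 6 with SD 1.5
  (a realistic dynamic range), 3 replicates per arm, planted |log2FC| = 2
  on 400 of 2000 genes, and a two-level batch factor with per-gene log2
  effects of SD 0.15.
- `simulate_cohort()`: log-scale Gaussian expression; CRPC-NE samples
  shifted on signature genes by `effect_size_sd` (default 1.5) within-state
  SDs, sign-concordant with gene direction — so in the simulation CRPC-NE
  occupies the *high* class, whereas the motivating study observed it in
  the low class; the extreme-quartile contingency test is symmetric in the
  class labels, so downstream behaviour is unaffected. Each sample carries
  a latent aggressiveness (state severity plus standard normal) from which
  the ordinal Gleason grade group is drawn through a proportional-odds
  link (cutpoints −2, −0.75, 0.75, 2) and the continuous risk score
  through a logistic link, giving the trend and rank tests an honest,
  noisy association to detect.
- `simulate_coip_peptides()`: log-normal intensities (protein baselines
  N(24, 2) on log2, peptide offsets N(0, 1), replicate noise SD 0.5),
  partner enrichment +3 log2 in the IP, and dropout probability
  `plogis(-steepness (log2 I - midpoint))`, strictly decreasing in
  intensity. A midpoint of −∞ means no dropout regardless of steepness
  (the logistic expression is indeterminate there, so the limit is taken).
- `simulate_dimethyl_psms()`: gamma channel S/N, with deliberately planted
  low-PSM proteins, low-S/N PSMs, and control-absent partners, to exercise
  every filter branch.
- `simulate_loh_calls()`: per-gene Bernoulli loss-of-heterozygosity calls
  with planted per-state fractions, split evenly between hemizygous
  deletion and copy-number-neutral LOH.

What the generators do *not* emulate: platform batch structure across
cohorts, gene–gene correlation, microarray-vs-RNA-seq calibration,
peptide-level interference, or realistic censoring patterns (survival
times in the tests are exponential with administrative censoring only).
Passing tests therefore demonstrate that the pipeline recovers planted
structure under its own model assumptions — not that those assumptions
hold in any particular clinical dataset.

Everything stochastic is seeded. Pipeline stages receive seeds derived
from the global seed and the stage name by a small documented string hash,
so each stage is reproducible independently of stage order, and a rerun
with the same configuration reproduces every artifact byte for byte.

## Problem sizes and test design

The test and acceptance workloads are sized for a desk-scale run: null
calibration uses 5000 features across 10 seeds (50,000 tests), signature
recovery uses 20 cohorts of 180 samples with 100 signature genes over 400
background genes, the imputation contract draws 100,000 values per level,
enumeration oracles cover 200 random small tables/samples, and the
Mann–Kendall check compares against 10⁵ permutations per series. The
cohort-scale published quantities (the TCGA trend p-value, the Decipher
enrichment percentages, the hazard ratio, and the 419-gene list itself)
depend on controlled-access patient data and are not reproducible here;
what is reproduced instead are the two extreme-quartile contingency tables
rebuilt from printed counts, and property-level guarantees on every
statistical component.

## Known limitations

- The moderated-t engine is a stand-in for a count-based quasi-likelihood
  test; rankings agree well at these effect sizes but p-values are not
  interchangeable with the NB model's.
- Sign weights discard fold-change magnitude; `weight_mode = "log2fc"` is
  available but changes score scale, not class boundaries, in most cohorts.
- The Mann–Whitney and Mann–Kendall exact paths are enumeration-bound
  (combined n ≤ 12, series n ≤ 8 by default); beyond that the tie-corrected
  normal approximations apply.
- `significance_curve()`'s constant uses the overall SD of fold changes,
  which is inflated by very strong true enrichments in small tables; with
  hundreds of proteins this effect is negligible.
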