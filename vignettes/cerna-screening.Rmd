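---
title: "Consensus screening of ceRNA axes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus screening of ceRNA axes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernascreen)
```

## The problem

Long non-coding RNAs (lncRNAs) that act as miRNA sponges couple the
abundance of the RNAs sharing their miRNA response elements: under the
competing-endogenous-RNA (ceRNA) hypothesis, a sponge lncRNA and the mRNAs
it protects should be *positively* correlated, while the shared miRNA
should be *negatively* correlated with both. `cernascreen` implements a
desk-scale pipeline that exploits this signature to nominate candidate
tumor-suppressor (or oncogene) lncRNAs from a heterogeneous collection of
expression datasets and to reconstruct their lncRNA–miRNA–mRNA axes, plus
the 2^-ΔΔCt statistics used to validate such candidates by qPCR.

The pipeline has three in-silico stages:

1. **Bait-gene screen.** In each dataset, every protein-coding gene is
   tested by one-way ANOVA against a binary severity contrast (e.g.
   metastasis M1 vs M0, MSI vs MSS, mutated vs wild-type). For two groups
   the F statistic equals the square of the pooled-variance t statistic.
   p-values are Benjamini–Hochberg adjusted within each
   dataset × contrast, and a gene is called at q ≤ 0.01. Genes called in
   the same direction in at least 50% of consulted datasets become the
   up- and down-regulated *bait genes* (BGs). This is deliberate
   vote-counting, not meta-analytic effect pooling: it mirrors how
   multi-platform repository collections are actually screened, where
   effect sizes are not comparable across platforms.

2. **lncRNA selection.** Every lncRNA is correlated (Pearson, two-sided
   t-transform p-value) with every bait in every dataset; a
   (lncRNA, bait, sign) triple is retained when significant (p < 0.01)
   with that sign in ≥ 50% of datasets. Retained triples populate four
   signed lists — A: positive with down-baits, B: positive with up-baits,
   C: negative with down-baits, D: negative with up-baits — and the
   intersections A∩D and B∩C give tumor-suppressor and oncogene
   candidates respectively. An lncRNA qualifying for both intersections is
   reported as a `conflict`, never silently dropped: the packaged
   published-table fixture shows why this channel matters, since one
   lncRNA sits in both B and C yet was absent from the originally stated
   oncogene set (`run_table2_fixture()` flags it with `reported = FALSE`).

3. **Axis reconstruction.** For a candidate lncRNA, miRNAs are selected by
   negative correlation (p ≤ 0.001) in the designated complete,
   miRNA-bearing dataset, then *unioned* with binding-site predictions —
   union, not intersection, because published axis tables retain miRNAs
   whose correlation support alone would be too weak. miRNAs with no
   validated mRNA target are excluded; the remainder are restricted to
   documented disease-involved miRNAs (oncomiRs). An axis is emitted per
   (miRNA, validated-target mRNA) pair whose mRNA is positively and
   significantly correlated with the lncRNA in ≥ 50% of datasets. The
   negative miRNA–mRNA requirement is **soft by default**: published axis
   tables include non-negative miRNA–mRNA correlations, so the constraint
   is recorded per axis as `strict_pass` and only enforced with
   `strict = TRUE`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha_de` | 0.01 | q-value cutoff of the per-dataset ANOVA screen |
| `use_fdr` | `TRUE` | apply the DE cutoff to adjusted q (not raw p) |
| `alpha_corr` | 0.01 | p cutoff for lncRNA–bait and lncRNA–mRNA correlations |
| `alpha_mirna` | 0.001 | p cutoff for the negative lncRNA–miRNA screen |
| `min_fraction` | 0.5 | cross-dataset support threshold ("at least 50%") |
| `strict` | `FALSE` | enforce negative miRNA–mRNA correlation in axes |
| qPCR significance | 0.05 | flag attached to each group comparison |

The DE filter wording "filtered by p-value (≤ 0.01) using the false
discovery rate as correction" is ambiguous between raw-p and adjusted-q
thresholds; this package defaults to q ≤ 0.01 (the correction *is* the
criterion) and exposes `use_fdr = FALSE` for the raw-p reading. Support
fractions are compared with a tolerance of one machine epsilon so that
exact ties like 6/12 ≥ 0.5 never fail by floating-point accident. One
retained bait association of the matching type suffices for list
membership; the published flat lists do not record per-bait multiplicity,
so requiring more would be an unstated extra filter.

Inputs are assumed to be on log scale; `log2_transform = TRUE` at read
time applies `log2(x + 1)` for linear-scale matrices. Correlation screens
are scale-sensitive, so the package never transforms silently. Missing
values use the token `NA` and are pairwise-deleted per correlation; a
correlation is only reported with at least three complete pairs, and
constant vectors raise a distinct degenerate-input error rather than a
spurious coefficient.

## The synthetic cohort generator

`generate_cohort()` draws the structure every stage assumes, with planted,
serialized ground truth (`planted_truth`):

* expression is additive Gaussian on the log scale:
  `x = mu_gd + delta_gd * severe + lambda_g * f_s + e`, where `f_s` is a
  shared standard-normal latent factor per sample;
* bait genes receive a severe-group shift of `bait_effect_size` (default
  1.5) within-group SDs, jittered ±20% per dataset, with per-dataset
  baselines `mu_gd ~ N(8, 1)` emulating platform heterogeneity;
* the sponge lncRNA, its axis mRNAs and the down-baits load
  `+sponge_coupling` (default 0.8) on the factor; axis miRNAs and up-baits
  load `-sponge_coupling`; decoys load 0. Two features with loadings
  `l1, l2` then have population correlation
  `l1 l2 / sqrt((l1^2 + s^2)(l2^2 + s^2))`; at the defaults
  (`noise_sd = 1`) this is ≈ 0.39, deliberately in the range of
  correlation coefficients reported for real sponge axes (≈ 0.2–0.57)
  rather than an unrealistically clean signal;
* the first dataset plays the complete, miRNA-bearing compendium (no
  missing features, all biotypes), mirroring the role a TCGA-style
  collection plays against array-based collections that lack miRNA probes;
  the remaining datasets are mRNA/lncRNA-only and drop each feature with
  probability `missing_feature_fraction` (default 0.1);
* interaction tables contain every planted pair plus decoy rows, the
  validated-target table deliberately omits rows for
  `n_mirnas_without_targets` miRNAs to exercise the exclusion rule, and
  the cancer table annotates the planted oncomiRs for the study disease.

Default cohort size — 8 datasets, 60 samples per severe/mild group — is
the screening regime the pipeline is designed for: enough datasets for a
meaningful 50% vote, per-dataset sample sizes typical of public tumor
collections. All randomness flows from one master seed through
`sub_seed(seed, stage, index)`, a documented integer hash, so adding a
stage never perturbs the draws of another and identical seeds give
identical bytes.

What the generator does *not* emulate: probe-level artifacts, batch
effects, RNA-seq count distributions (everything is Gaussian on log
scale), correlated decoys, or identifier aliasing. Passing recovery tests
therefore demonstrate the screening logic — voting, set algebra, sign
constraints, funnel filters — under the assumed statistical model, not
robustness to real-data pathologies such as normalization failures or
annotation mismatches.

```{r recovery}
cfg <- cohort_config(seed = 7)
cohort <- generate_cohort(cfg)
tables <- generate_interaction_tables(cohort$truth, cfg)
run <- suppressMessages(run_screen(
  cohort$datasets, contrast_spec("severity", "severe", "mild"),
  tables$binding, tables$targets, tables$cancer
))
glance(run)
tidy(run)
```

## qPCR relative quantification

`delta_ct()` averages technical replicates arithmetically before
subtracting the reference gene (a convention — the mean-of-replicates rule
is not a claim about any particular instrument's software);
`fold_change()` is the plain `2^-ΔΔCt` with group-mean ΔCts; and
`compare_groups()` is Student's pooled-variance t-test (Welch selectable)
or a paired t-test on within-pair differences. No amplification-efficiency
correction is attempted. Exact identities — ΔΔCt = 0 ⇒ fold change 1,
`fc(a,b)·fc(b,a) = 1`, invariance to a global Ct shift — are enforced by
tests, and noise-free synthetic plates invert exactly.

## Numerical and degenerate-input choices

* Pearson p-values come from the t-transform with `n − 2` degrees of
  freedom (`cor.test`'s method), not permutation; coefficients of exactly
  ±1 map to p = 0.
* `fdr_adjust()` is the Benjamini–Hochberg step-up (`p.adjust`), checked
  in tests against an independently coded literal `min_{j≥i}(m·p_(j)/j)`.
* Features constant within a contrast are excluded with a log message
  (they carry no usable signal; F would be 0/0).
* A group with fewer than two samples skips the whole contrast with a
  warning — the dataset simply contributes no calls.
* An axis whose required miRNA–mRNA correlation record is unavailable is
  skipped and logged, never fabricated.
* Axis statistics are reported from the designated complete dataset when
  it supports the pair, otherwise from the supporting dataset with the
  median coefficient — so every reported number is a real computed record.

## Known limitations

* Marginal Pearson only: no partial correlation or covariate adjustment,
  so confounding (e.g. tumor purity) can induce spurious lists.
* Vote counting weighs a 40-sample dataset equally with a 400-sample one.
* Identifier matching is case-insensitive trimming only; no alias
  resolution across annotation vintages.
* Binding evidence is consumed as given; no de-novo site prediction.
* The problem sizes used by the test-suite recovery studies (20 seeded
  replicates of the default cohort; 1,000-replicate type-I simulations)
  were chosen as the package's own benchmark scale; larger studies
  reproduce by raising the counts.
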