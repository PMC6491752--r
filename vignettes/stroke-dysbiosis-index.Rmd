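---
title: "Methods: constructing and evaluating a stroke dysbiosis index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing and evaluating a stroke dysbiosis index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdindex)
library(dplyr)
```

## The model

Gut dysbiosis after acute ischemic stroke is broad: dozens of genera shift
at once, which makes per-genus readouts hard to use clinically. The Stroke
Dysbiosis Index (SDI) condenses a case-control dysbiosis pattern into one
number per sample. Given a directional signature — a set $S$ of
stroke-enriched genera and a set $C$ of control-enriched genera — and a
sample's percent relative abundances $a_g$,

$$\mathrm{SDI} \;=\; \left( \frac{1}{|S|} \sum_{i \in S} a_i \;-\;
\frac{1}{|C|} \sum_{j \in C} a_j \right) \times 100 .$$

Higher values mean a community tilted toward the stroke-associated pattern.
The packaged signature (`preset_signature()`) has $|S| = 7$ and $|C| = 11$;
any signature produced by `select_signature()` uses its own side sizes as
denominators. Two conventions deserve a note:

* **Abundance units are percent (0–100).** With fractional abundances in
  $[0,1]$ the index maximum would be $(1/7) \times 100 \approx 14.3$, which
  cannot reach the patient median of 17.0 reported for the original
  training cohort; percent units place published medians inside the
  attainable range $[-100 \cdot 100/11,\; 100 \cdot 100/7]$.
* **Missing signature genera contribute zero** while denominators stay
  $|S|$ and $|C|$. This keeps scores comparable across cohorts — a
  validation cohort that happens to lack a signature genus is still scored
  on the training scale. (A direct consequence is that swapping $S$ and $C$
  exactly negates the index for any side sizes, since each mean travels
  with its own set.)

## The pipeline

The preprocessing order is fixed as *filter → rarefy → relative abundance*:

1. `filter_low_abundance()` keeps a genus iff its total count is at least
   `min_count_fraction` (default 0.001) of the table's **grand** total —
   the table-wide semantics of the QIIME 1 filtering command, with an
   inclusive boundary.
2. `rarefy_counts()` subsamples each sample without replacement to `depth`
   reads (default 4800 for the index pipeline; community-diversity analyses
   conventionally use 8000 — both are plain arguments, and the package
   honors whichever the analysis calls for rather than resolving the
   discrepancy). Samples below depth are **dropped**, loudly. Each sample
   draws from an RNG stream derived from `(seed, sample_id)`, so sample
   order can never change a result.
3. `to_relative()` converts to percent; every surviving row sums to 100.

Signature selection (`select_signature()`) runs a per-genus Wilcoxon
rank-sum test between groups on the percent abundances, adjusts with
Benjamini–Hochberg, and admits genera with adjusted $p$ strictly below 0.1.
Direction is the group with the larger **mean** relative abundance — the
mean is what the index formula averages, so this keeps the signature
self-consistent; a median rule is available via `direction_stat`. A genus
significant with exactly equal group summaries has no direction and is
excluded with a warning. The two-group Wilcoxon is what the
Kruskal–Wallis-based selection command reduces to for two groups, up to tie
handling.

`stratify_by_median()` splits patients at their median score, ties going to
the high stratum (`SDI-H`), matching the published $\ge$ convention.
Whether a validation cohort should be scored with the training signature or
a re-derived one is not fixed by the source material; the package's default
workflow applies the **training** signature (simply pass it to
`compute_sdi()`), which is the choice that makes external validation
meaningful.

## Evaluation battery

* `roc_analysis()` — trapezoid AUC over the full threshold sweep; the AUC
  equals the tie-averaged Mann–Whitney $U/(n_1 n_2)$, and the test suite
  asserts that identity on random instances.
* `spearman_cor()` — midrank Spearman correlation of the index with NIHSS
  on admission (0–42) and mRS at discharge (0–6).
* `summarize_groups()` — baseline-table comparisons: Shapiro–Wilk gates
  continuous variables between mean (SD)/t-test and median (IQR)/Wilcoxon
  (which of the two tests produced each published table row is not
  itemized in the source; the Shapiro gate is this package's documented
  rule); categorical variables use chi-square, or Fisher's exact test when
  any expected *or observed* cell count falls below 5 (the observed-cell
  clause is the common clinical convention and is required for small
  2×2 tables whose expected counts are exactly 5).
* `univariate_screen()` + `logistic_fit()` — candidate covariates with
  univariate $p < 0.20$ enter a multivariable logistic model (severity
  outcome: NIHSS $\ge 8$; unfavorable outcome: mRS $> 2$; NIHSS/mRS are
  never predictors because they define the outcomes). Estimates are
  reported as odds ratios with Wald 95% intervals; laboratory covariates
  enter untransformed. Perfect separation is detected through a
  near-zero residual deviance (the IRLS loop can converge before fitted
  probabilities reach machine epsilon, so the usual glm warning alone is
  not a reliable detector) and raised as an explicit error naming the
  covariate; the univariate screen converts that error into an
  infinite-odds-ratio flag instead of failing. No multiplicity adjustment
  is applied in the clinical battery — FDR control belongs to signature
  selection only.
* `unifrac_distances()`, `pcoa_ordination()`, `permanova_test()`,
  `distances_to_reference()` — unweighted UniFrac (presence = count > 0)
  against a genus-level tree, classical-scaling PCoA with negative
  eigenvalues reported and omitted, permutation PERMANOVA with
  $p = (\#\{F_{perm} \ge F_{obs}\} + 1)/(B + 1)$ and a fixed seed, and
  all-pairs patient-to-control distance comparisons per stratum (a
  per-patient-mean summary would be the natural alternative; all pairs is
  the default because it uses every distance the metric produces).

## The synthetic cohort generator

`simulate_cohort()` exists so that every downstream stage is testable
without the original sequencing data. It draws genus counts from a
Dirichlet–multinomial model: per-sample Dirichlet proportions around a base
concentration vector (total concentration 200, giving visible
overdispersion relative to a plain multinomial), then multinomial sampling
at a depth drawn uniformly from 8000–15000 so that rarefaction is exercised
non-trivially. Case samples multiply stroke-enriched planted concentrations
by $2^{\text{effect\_log2fc}}$ and divide control-enriched ones likewise.
Unplanted genera take log-normal concentrations with a long lower tail, so
a realistic fraction of genera (about a quarter at the defaults) falls
below the 0.1% filter and that stage does real work.

Default cohort sizes are 104/90 (training) and 83/70 (validation), matching
the study design the package addresses. The planted signature defaults to
the packaged 18-genus preset. Clinical scores are linked to each sample's
*true* index (computed from realized relative abundances and the planted
signature): NIHSS on admission is a rounded, clipped linear function of the
z-scored true index (intercept 4, slope 2.5 points per SD, noise SD 6.5 —
chosen so the synthetic Spearman correlation lands in the 0.2–0.45 range
reported for real cohorts, and so roughly a quarter of patients are severe);
mRS at discharge comes from proportional-odds thresholds on a latent
logistic score (slope 0.8 per SD; cutpoints put about 25% of baseline
patients above mRS 2, the unfavorable-outcome prevalence of the combined
real cohort). Because the mRS link is exactly a logistic latent model, the
dichotomized outcome regression is correctly specified and the test suite
checks that `logistic_fit()` recovers the planted slope within 2 SE.

What the generator does **not** emulate: phylogenetic correlation between
genus abundances (the tree from `simulate_genus_tree()` is random),
covariate–outcome confounding (covariates follow group-level marginal
patterns but are conditionally independent of outcome given group),
read-level artifacts, and compositional correlation structure beyond what
the Dirichlet induces. One visible consequence: the planted effects are
abundance-level shifts on mostly common genera, so **unweighted UniFrac —
a presence/absence metric — carries almost no case-control signal on
default synthetic cohorts** (PERMANOVA $R^2 \approx 0.005$). That is a
property of the metric, not a bug; community-level tests therefore use
constructed presence-level differences (disjoint or partially flipped
genus sets), mirroring the transplant experiment where donor communities
genuinely differ in membership.

## Numerical choices and degenerate inputs

* Filtering boundary inclusive (`total >= fraction * grand_total`).
* Rarefaction: sample at exactly the target depth is returned unchanged;
  all samples below depth is an error.
* All-identical score vectors cannot be stratified (error), all-identical
  group values give a degenerate rank-sum comparison with $p = 1$ and a
  flag.
* Constant input to the Spearman correlation warns and returns `NA`.
* Zero-total samples cannot be converted to relative abundance (error).
* PCoA on an all-zero distance matrix returns all-zero coordinates.
* The edema-corrected infarct area is floored at zero per section before
  integration over the section interval.

## Problem sizes

The test suite runs cohorts at 104/90 (full scale) where the claim depends
on it — planted-signature recovery (20 seeds, median $\ge 80\%$ at effect
log2FC 1), end-to-end training/validation discrimination (AUC > 0.70 both) —
and at 30–40 per group elsewhere; null calibration uses 50 seeds of
30/30 × 200-genus cohorts; UniFrac tests use 5–24 samples on 8–20-leaf
trees, where the hand oracle is checkable. The whole suite completes in
about a minute; `scripts/acceptance.R` reruns the headline pipeline from
scratch in a few seconds.
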