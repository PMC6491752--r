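# sdindex

Gut microbiome dysbiosis after acute ischemic stroke is broad and
heterogeneous: dozens of genera shift at once, which makes raw 16S profiles
hard to use in clinical work. `sdindex` condenses a case-control dysbiosis
pattern into a single per-sample score — the **Stroke Dysbiosis Index
(SDI)** — and implements the full pipeline around it, from genus-level
count tables to clinical outcome models. It is aimed at microbiome
researchers and clinical statisticians who have genus-collapsed 16S
abundance tables (TSV or BIOM-style JSON) and per-sample clinical metadata.

Given a directional signature — a stroke-enriched genus set *S* and a
control-enriched set *C* — and percent relative abundances *a*:

```
SDI = ( mean_{i in S} a_i  -  mean_{j in C} a_j ) × 100
```

The packaged signature (`preset_signature()`) has |S| = 7 and |C| = 11.
Around the index, the package provides:

- **Preprocessing** in the canonical order: grand-total low-abundance
  filtering (default 0.1%), rarefaction without replacement (default
  4800 reads; 8000 conventional for diversity analyses), percent relative
  abundance; plus genus collapse with the `Un <Family>` convention for
  genera unclassified below family rank.
- **Signature selection**: per-genus Wilcoxon rank-sum tests,
  Benjamini–Hochberg FDR, strict 0.1 threshold, direction by larger group
  mean.
- **Scoring and stratification**: Eq. above per sample; median split of
  patients into SDI-H / SDI-L (ties high).
- **Community ecology**: unweighted UniFrac, PCoA, PERMANOVA (Adonis),
  stratum-to-control distance comparisons.
- **Clinical evaluation**: ROC/AUC, Spearman correlation with NIHSS/mRS,
  baseline characteristics tables, univariate screening (p < 0.20) plus
  multivariable logistic regression with Wald 95% CIs, and the
  edema-corrected infarct volume formula used in companion animal
  experiments.
- **A synthetic cohort generator** (Dirichlet-multinomial counts with a
  planted signature and clinical scores linked to the true index) so the
  whole pipeline is testable without access to the original sequencing
  data.

Functions are tibble-first and pipe-friendly; fitted objects support
`tidy()` / `glance()`, and result objects have `autoplot()` methods.

## Worked example

Simulate a training cohort at the study's design size (104 patients, 90
controls), run the pipeline, and evaluate:

```r
library(sdindex)
library(dplyr)

coh <- simulate_cohort(cohort_spec(seed = 1))
rel <- coh$counts |>
  filter_low_abundance(0.001) |>
  rarefy_counts(4800, seed = 1) |>
  to_relative()

sig <- select_signature(rel, coh$clinical)
scores <- compute_sdi(rel, sig) |>
  left_join(coh$clinical, by = "sample_id")

scores |> group_by(group) |> summarise(median_sdi = median(sdi))
#> 1 control      -20.1
#> 2 stroke        90.1

roc_analysis(scores)
#> <sdi_roc> AUC = 99.0% (104 positive, 90 negative)

pat <- filter(scores, group == "stroke")
spearman_cor(pat$sdi, pat$nihss_in)
#>     rho p_value     n
#> 1 0.286 0.00330   104

strat <- stratify_by_median(pat[c("sample_id", "sdi")])
table(strat$stratum)
#> SDI-H SDI-L
#>    52    52

tidy(logistic_fit(pat, "unfavorable", c("sdi", "wbc", "age")))
#> sdi  estimate 0.0290  odds_ratio 1.03  conf 1.01-1.05  p 0.000377
```

Patients score well above controls on the index; discrimination is strong
because the synthetic effect is strong (a twofold planted shift on 18
genera). The Spearman rho of 0.286 reflects the generator's calibrated
severity link (real cohorts report 0.2–0.45). The 104 patients split
exactly 52/52 at the median, and the index remains an independent predictor
of unfavorable outcome (mRS > 2) after adjustment — an odds ratio of 1.03
per SDI point.

To score a new cohort with the published signature instead of a re-derived
one:

```r
scores <- compute_sdi(rel_new_cohort, preset_signature())
```

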