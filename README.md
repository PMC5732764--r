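# metdysreg

Metabolic dysregulation scoring and recurrence kinetics for prostate-cancer
studies.

Folate feeds one-carbon metabolism, which supplies dTMP for DNA synthesis and
S-adenosylmethionine for methylation and polyamine biosynthesis. In
castration-recurrent prostate cancer these pathways are heavily rewired, and
dietary folate manipulation changes both the kinetics of xenograft recurrence
after androgen withdrawal and the tumor methylome. `metdysreg` packages the
quantitative machinery needed to study this end to end:

* **Differential expression** (`scale_normalize`, `logcpm_transform`,
  `fit_moderated_t`, `diff_expression`): TMM scale factors, log-CPM
  transformation, and an empirical-Bayes moderated t-test. Per-gene residual
  variances `s_g²` (d_g df) are shrunk toward a prior `s₀²` with `d₀` prior
  df estimated by moment matching on `log s_g²`,
  `s̃_g² = (d₀ s₀² + d_g s_g²) / (d₀ + d_g)`, and
  `t_mod = log2FC / (s̃_g c_g)` is referred to `t` on `d_g + d₀` df, with
  Benjamini–Hochberg FDR adjustment.
* **Gene and pathway dysregulation scores** (`gene_scores`, `pathway_score`,
  `cross_cohort_table`): the signed score
  `s_g = log2FC_g · (−log₁₀ padj_g)`, its absolute value, and pathway totals
  `Σ s_g / √n` over the `n` pathway genes scored, comparable across cohorts;
  cohorts are ranked per pathway.
* **Survival stratification** (`normal_relative_zscores`,
  `patient_pathway_score`, `quartile_stratify`, `km_estimate`,
  `logrank_test`, `stratify_cohort`): per-patient scores
  `Σ|z_g| / √n` from normal-relative z-scores, quartiles (Q1 = low, Q4 =
  high dysregulation), Kaplan–Meier curves of 5-year biochemical-recurrence
  -free survival, and the Q1-vs-Q4 log-rank test.
* **Differential methylation** (`call_variable_positions`,
  `annotate_calls`, `hypergeometric_overlap`, `enrich_gene_sets`,
  `overlap_network`): variable CpG positions called when the beta value
  changes by more than 0.30 (absolute) versus the control-group mean in at
  least two animals of a diet group, hyper/hypo per direction; gene
  annotation, exact hypergeometric overlap tests, over-representation
  analysis, and an overlap-coefficient network export.
* **Xenograft kinetics** (`tumor_volume`, `classify_trajectory`,
  `interval_status_summary`, `fisher_exact`, `welch_t`, `pearson_r`):
  caliper volumes (`length² × width × 0.5234`), the four-threshold event
  classification (initial response < 300 mm³, regression < 150 mm³, complete
  regression < 100 mm³, recurrence > 500 mm³ after regression), 4-weekly
  status summaries, and the supporting exact/t/correlation tests.
* **Synthetic data** (`simulate_expression_cohort`, `simulate_survival`,
  `simulate_methylome`, `simulate_xenograft_trajectories`,
  `simulate_study`): seeded generators with ground-truth tables for every
  stage, so the whole pipeline is testable without external downloads.

## Worked example

Simulate a 100-pair tumor/normal cohort with half of a 30-gene folate
pathway perturbed at |log2FC| = 1.5, score it, and relate the per-patient
dysregulation to simulated biochemical recurrence:

```r
library(metdysreg)

folate <- paste0("g", 1:30)
sim <- simulate_expression_cohort(expr_sim_config(
  n_genes = 2000, n_pairs = 100,
  pathway_defs = list("Folate Metabolism" = folate),
  effect_frac = 0.5, effect_scale = 1.5, seed = 42))

de <- diff_expression(sim$cohort)
de
#> DEResult: 2000 genes (100 tumor vs 100 normal)
#>   prior df d0 = 807.6, prior variance s0^2 = 0.2255
#>   genes at padj < 0.05: 16

pathway_score(gene_scores(de), folate, mode = "absolute",
              name = "Folate Metabolism")
#>             pathway n_genes_scored    total
#> 1 Folate Metabolism             30 358.9849

z <- normal_relative_zscores(sim$cohort)
ps <- patient_pathway_score(z, folate, name = "Folate Metabolism")
ps$quartile <- quartile_stratify(ps$score)
surv <- simulate_survival(setNames(ps$score, ps$patient_id),
                          surv_sim_config(100, baseline_hazard = 0.15,
                                          seed = 42))
lr <- logrank_test(surv[ps$quartile == "Q1", ], surv[ps$quartile == "Q4", ])
sprintf("Q1 vs Q4 log-rank: chi2 = %.2f, p = %.4g", lr$chi2, lr$p)
#> "Q1 vs Q4 log-rank: chi2 = 12.52, p = 0.0004033"
```

The 16 genes recovered at `padj < 0.05` are (up to sampling noise) the 15
planted pathway genes; the planted pathway carries a large absolute
dysregulation score, and the patients in the top dysregulation quartile
recur significantly faster than those in the bottom quartile (21 versus 9
events of 25), exactly the behavior the scoring is designed to expose.

A published-scale overlap check runs in microseconds: 766 methylation-
derived genes against an 861-gene meta-analysis list with 270 shared in a
20,000-gene universe gives

```r
hypergeometric_overlap(766, 861, 20000, overlap = 270)$p_upper
#> 1.34e-181
```

far below the p < 0.001 usually quoted for such overlaps.

Three editable GMT pathway fixtures (folate, folate one-carbon, polyamine)
ship under `inst/extdata/metabolic_pathways.gmt`; `read_gmt()` loads any
standard GMT collection. `simulate_study()` drives all four generators from
a single YAML file and writes TSV/CSV outputs plus truth tables.

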