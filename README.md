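# cyp21act

Structure-based prediction of residual 21-hydroxylase activity for
CYP21A2 missense variants, from protein-stability changes (ΔΔG).

## Why

21-hydroxylase deficiency, the commonest cause of congenital adrenal
hyperplasia, spans a phenotypic spectrum that tracks residual enzyme
activity: ~0% in salt-wasting (SW), ~2% in simple-virilizing (SV), and
10–60% in non-classical (NC) disease. Most reported *CYP21A2* missense
variants have no functional assay. For the subset whose only plausible
mechanism is destabilization of the folded protein, the folding
free-energy change on mutation (ΔΔG, kcal/mol, positive = destabilizing,
estimated by a predictor such as FoldX from the human crystal structure
or a bovine-template model) can be converted into an expected residual
activity through a log-linear calibration:

    ln(activity %) = a + b·ΔΔG

fitted by unweighted least squares with ΔΔG clamped at 5.5 kcal/mol
(where measured activities saturate near 0%), predictions capped at 100%,
a 1.6 kcal/mol destabilization cutoff (twice the predictor SD, strict),
activities > 75% called non-pathogenic, and permutation tests for the
significance of the Spearman correlation and the regression slope.

The package is aimed at structural/clinical bioinformaticians curating
P450 variants. It provides, as tidyverse-style functions over tibbles:

- `parse_protein_variant()`, `read_variant_table()`,
  `write_report_table()` — protein-level variant labels and
  variant/activity tables (TSV/CSV);
- `load_structure()`, `is_heme_or_ligand_contact()`,
  `is_por_interface()`, `classify_variant()` / `classify_table()` —
  structural context (heme contact, POR interface, motifs) isolating the
  stability class;
- `read_ddg_table()`, `aggregate_replicas()`, `is_destabilizing()` —
  FoldX-style output ingestion and five-replica aggregation;
- `fit_calibration()`, `predict_activity()`, `call_pathogenicity()`,
  `spearman_rho()`, `permutation_pvalue()` — the calibration, with
  `tidy()`/`glance()`/`autoplot()` methods;
- `additive_baseline()`, `synergy_score()`, `classify_double()` — two
  variants in cis: additivity, synergy, scenario taxonomy;
- `synthetic_spec()`, `generate_calibration_pairs()`,
  `generate_replicas()`, `generate_toy_structure()`,
  `generate_double_variant_set()` — synthetic inputs for every stage;
- `run_config()` / `run_pipeline()` — end-to-end orchestration with a
  provenance manifest (a thin CLI wrapper lives in `inst/cli/cyp21act.R`).

See the vignette in `vignettes/ddg-activity-calibration.Rmd` for the full
methods account.

## Worked example

Refit the shipped reference table (19 informative rows of the published
in-silico activity table) and predict new variants:

```r
library(cyp21act)

pairs <- table2_fit_set()          # printed activity in [0.05, 100), ddG <= 5.5
model <- fit_calibration(pairs, seed = 1)
model
#> ddG -> activity calibration (n = 19, cap 5.5 kcal/mol)
#>   ln(activity%) = 5.3879 -1.5458 * ddG
#>   R^2 = 1.000; Spearman rho = -1.000 (p = 9.999e-05); slope p = 9.999e-05

predict_activity(model, c(4.94, 5.34, -2.16)) |> call_pathogenicity()
#> # A tibble: 3 × 6
#>   ddg_mean activity_pred_pct capped display pathogenicity_call   severity_band
#>      <dbl>             <dbl> <lgl>  <chr>   <chr>                <chr>
#> 1     4.94            0.106  FALSE  0.1     pathogenic_candidate SW_like
#> 2     5.34            0.0569 FALSE  0.06    pathogenic_candidate SW_like
#> 3    -2.16          100      TRUE   ≥100    non_pathogenic       normal_like
```

A ΔΔG of 4.94 kcal/mol maps to ~0.1% residual activity (an SW-like
allele); a stabilizing ΔΔG of −2.16 saturates the cap and is reported as
"≥100" (non-pathogenic). Two benign polymorphisms combined in cis:

```r
classify_double(tibble::tibble(ddg_1 = 0.81, ddg_2 = 0.74, ddg_double = 1.55))
#>   additive_sum = 1.55, scenario = additive_nonpathogenic,
#>   pathogenic_combined = FALSE, near_cutoff = TRUE
```

— individually harmless, but their sum sits a whisker below the 1.6
kcal/mol cutoff, hence the `near_cutoff` flag.

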