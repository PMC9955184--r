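# cytopops

Explainable discovery of prognostic cell populations in multiparameter
flow cytometry (MPFC) data, with chronic lymphocytic leukemia (CLL) as
the motivating setting.

Routine diagnostic B-cell panels measure light scatter and a dozen or
more surface antigens on up to 10^5 cells per patient. Buried in those
events are cell populations whose per-patient frequency carries
prognostic information — for example, the fraction of CD4+ T helper
cells, which is higher in patients with a superior clinical course.
`cytopops` finds such populations automatically while keeping every
result expressible as a chain of rectangular gates on ordinary 2D dot
plots, so a cytometrist can verify each population by conventional
manual gating.

## What the package does

For a cohort of samples labelled by clinical outcome (TTF 1 = death
during follow-up and/or failure of first-line therapy; TTF 0 =
neither), the pipeline:

1. **Reads / writes FCS 3.0/3.1** event files and CSV metadata
   (`read_fcs()`, `write_fcs()`, `read_metadata()`).
2. **Preprocesses** each sample: spillover compensation, log10
   transform of fluorescence, exclusion of very-high side-scatter
   events (granulocytes), per-channel range standardization onto
   [0, 6] with robust percentiles, and a 1% random training draw
   (`preprocess_sample()`).
3. **Discovers populations** with a greedy binary gate tree
   (`build_gate_tree()`): candidate gate edges are placed only in the
   valleys of the per-channel event density (populations are density
   modes; boundaries belong between modes), and among those
   mode-aligned candidate rectangles the split is chosen that
   maximizes the absolute Cohen's d, across samples and between
   outcome classes, of the per-sample frequency of events inside the
   rectangle:

   d = (mean₁ − mean₀) / s_pooled,
   s_pooled² = ((n₁−1)s₁² + (n₀−1)s₀²) / (n₁+n₀−2)

   Tree leaves partition the event space, so each sample gets a
   frequency vector summing to 100%.
4. **Selects the important few** populations by computed ABC analysis
   of the |d| values (`abc_analysis()`, `select_populations()`): the
   A/B boundary is the ABC-curve point closest to the ideal (0, 1),
   the B/C boundary the first break-even item.
5. **Evaluates** each population with Mann–Whitney U tests and ROC
   analysis — AUC via the rank formulation (AUC = U/(n₁·n₀)) with
   Hanley–McNeil confidence intervals and paired AUC comparison
   (`roc_auc()`, `compare_auc_paired()`) — plus multiple logistic
   regression with leave-3-per-group bootstrap validation
   (`fit_logistic()`, `bootstrap_validate()`), CLL-IPI scoring with
   half-point imputation for missing components (`ipi_score()`), and
   Table-1-style cohort summaries (`summarize_cohort()`).
6. **Characterizes** selected populations biologically: median marker
   profiles relative to the cohort-average CLL population, rule-based
   lineage annotation (CD4 T cell, CD8 T cell, CLL subset, ...), and
   dot-plot export with gate overlays (`population_profile()`,
   `annotate_lineage()`, `export_dotplots()`).

Because patient-level cytometry files of the motivating study are not
publicly deposited, the package ships a calibrated **synthetic cohort
generator** (`generate_cohort()`): 42 inferior / 115 superior samples
by default, each a mixture of named populations (CLL, apoptotic CLL,
prolymphocytoid CLL, CD4/CD8 T cells, NK, other) with class-dependent
logit-normal frequencies — the CD4-like population averages 13.51% in
TTF 0 vs 4.91% in TTF 1 and separates the classes at an analytic AUC
of about 0.78.

## Worked example

```r
library(cytopops)

cfg <- cohort_config(n_ttf1 = 42, n_ttf0 = 115,
                     events_per_sample = 5000,
                     tubes = "T1", output = "raw", seed = 1)
coh <- generate_cohort(cfg)
res <- run_pipeline(coh, tubes = "T1")
print(res)
#> == tube T1 ==
#> 6 populations; 4 selected: T1C0003, T1C0001, T1C0002, T1C0005
#>    pop_id      label
#> 1 T1C0003      T_CD4
#> 2 T1C0001      T_CD8
#> 3 T1C0002      T_CD8
#> 4 T1C0005 CLL_subset

r <- res$T1$ranking
r[r$pop_id == "T1C0003",
  c("mean_ttf1", "mean_ttf0", "cohens_d", "mwu_p", "auc")]
#>   mean_ttf1 mean_ttf0   cohens_d        mwu_p       auc
#> 3  5.217043  14.60577 -0.9272416 1.665499e-09 0.1851967
```

The recovered population `T1C0003` is annotated as CD4+ T cells; its
frequency averages 5.2% in the inferior-outcome group versus 14.6% in
the superior group (the generator plants 4.91% vs 13.51%), its AUC of
0.19 means the *scarcity* of CD4 T cells predicts the inferior outcome
(equivalently 0.81 with the protective direction), and its per-percent
odds ratio from a logistic fit is 0.84 — each percentage point of CD4
T cells lowers the odds of an inferior outcome by about 16%.

```r
ho <- heldout_lineage_auc(coh, "T1", "T_CD4", k = 5, seed = 1)
ho$auc
#> [1] 0.8119048
analytic_frequency_auc(cfg, "T_CD4")
#> [1] 0.7819798
```

The 5-fold held-out AUC of the recovered population (gates retrained
in every fold) matches the generator's analytic discriminability.

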