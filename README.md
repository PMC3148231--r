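# mirsig

Multi-tissue microRNA signature discovery for Type 2 Diabetes.

`mirsig` is a tidyverse-native R package for the analysis pattern used in
circulating-biomarker studies of metabolic disease: profile miRNA
expression in several tissue sources of a diabetic animal model (pancreas,
liver, adipose, skeletal muscle, blood) and in human whole-blood cohorts
(healthy controls, impaired fasting glucose, overt T2D), then reduce the
per-contrast differential lists to one cross-source, cross-species
signature and connect it to predicted mRNA targets and qPCR validation.

It is aimed at transcriptomics analysts who want each published filtering
rule as an explicit, tested function rather than a spreadsheet step.

## The method in brief

For each `(species, source)` stratum and case group, every detected miRNA
(mean background-subtracted intensity strictly above 300, before U6
geometric-mean normalization) receives:

- a **signed fold change** of linear group means — the ratio *r* reported
  as *r* when *r* ≥ 1 and as −1/*r* otherwise;
- a **two-tailed Welch p-value** on log2 intensities;
- a **replication fraction** — the share of case subjects whose individual
  ratio against the control mean lies strictly on the group's side of 1.

A miRNA survives a contrast when p < 0.05, |fc| ≥ 1.5, and the direction
replicates in at least 50% of subjects. The **cross-source signature**
keeps miRNAs passing all three filters in every source with one sign; the
**cross-species signature** keeps those whose direction agrees with the
significant human T2D blood contrast (IFG is recorded, not used for
exclusion). Predicted (miRNA, gene) pairs are accepted by **consensus
voting** — at least 3 of 5 prediction databases — and labeled `inverse`
when miRNA and target move oppositely. qPCR plates are reduced with
ΔCt → ΔΔCt → 2^−ΔΔCt arithmetic, SEM propagated by the delta method.

A synthetic-data generator plants the eight-miRNA diabetes signature
(up: miR-144, miR-150, miR-192, miR-29a, miR-320a; down: miR-146a,
miR-30d, miR-182) with published per-tissue magnitudes into a log-normal
intensity model, so the whole pipeline is benchmarkable against known
truth without any downloads. See `vignettes/mirsig-methods.Rmd` for the
full model description.

## Worked example

```r
library(mirsig)
library(dplyr)

rep <- run_pipeline(list(generator = list(seed = 1), qpcr = TRUE))
rep
#> <mirsig_report>
#>   contrasts: 1291 fold-change records
#>   signature: 8 concordant miRNAs

rep$signature %>%
  select(mirna_id, direction, fc_pancreas, fc_blood,
         human_t2d_fc, human_ifg_fc, concordant)
#>   mirna_id direction fc_pancreas fc_blood human_t2d_fc human_ifg_fc concordant
#> 1  miR-144        up        6.24     2.65         2.73         1.12       TRUE
#> 2  miR-150        up        2.34     2.36         2.54         2.98       TRUE
#> 3  miR-192        up        2.39     2.21         2.75         2.63       TRUE
#> 4  miR-29a        up        2.56     2.36         2.57         2.54       TRUE
#> 5 miR-320a        up        2.66     2.51         2.20         2.31       TRUE
#> 6 miR-146a      down       -2.25    -2.57        -2.25        -2.16       TRUE
#> 7  miR-30d      down       -2.87    -2.27        -2.61         1.95       TRUE
#> 8  miR-182      down       -2.26    -2.58        -2.28         2.22       TRUE
```

All eight planted miRNAs are recovered with the right directions and no
false positives. Note the biology the pipeline preserves: miR-144 is
strongest in pancreas, and miR-30d / miR-182 flip sign in the
pre-diabetic IFG column while concordance is keyed to T2D. The Venn
summary over the five rat sources,

```r
glance(rep$venn)
#>   n_sets union_size n_regions n_nonempty_regions all_sets_count
#> 1      5         52        31                  8              8
```

shows 52 miRNAs significant somewhere and exactly the 8 signature miRNAs
significant in all five sources at this noise level. The simulated qPCR
validation recovers the planted effects as 2^−ΔΔCt fold changes:

```r
rep$qpcr %>% filter(feature_id %in% c("miR-144", "miR-146a")) %>%
  select(feature_id, fold_change, signed_fc, sem)
#>   feature_id fold_change signed_fc    sem
#> 1    miR-144       3.576      3.58 0.3799
#> 2   miR-146a       0.359     -2.78 0.0321
```

`rep$dendrogram` (average linkage, Euclidean; also serialized as Newick)
clusters the human T2D blood profile among the rat peripheral-tissue
profiles, with pancreas merging later — the pattern that motivates using
blood as a window on tissue miRNA changes. `autoplot(rep$pca)` and
`plot_fold_change_heatmap(rep$records)` give the standard ordination and
green/red/grey heatmap views, and every result table is a tibble with
`tidy()`/`glance()` methods.

File-based inputs work the same way through `read_expression_matrix()`,
`read_sample_sheet()`, and `read_prediction_tables()`, with
`run_pipeline(list(mode = "files", expression = ..., samples = ...))`.

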