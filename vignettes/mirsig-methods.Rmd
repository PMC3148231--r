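---
title: "Methods: multi-tissue miRNA signature discovery with mirsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue miRNA signature discovery with mirsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsig)
library(dplyr)
```

## The problem

Circulating microRNAs are candidate non-invasive biomarkers of Type 2
Diabetes (T2D): whole-blood miRNA profiles track what happens in the
pancreas and the insulin-target tissues (liver, adipose, skeletal muscle).
`mirsig` implements, as a reusable and fully testable pipeline, the
analysis pattern behind that claim: profile miRNAs in several tissue
sources of a diabetic animal model and in human blood cohorts
(healthy/pre-diabetic IFG/overt T2D), filter each contrast for detection,
significance, magnitude and per-subject replication, intersect across
sources and species, and connect the surviving signature miRNAs to their
predicted mRNA targets and qPCR validation measurements.

Because real array deposits are not required to exercise any of this, the
package ships a first-class synthetic-data generator that plants a known
eight-miRNA signature (up: miR-144, miR-150, miR-192, miR-29a, miR-320a;
down: miR-146a, miR-30d, miR-182) into a realistic two-species design.
Every stage of the pipeline can therefore be benchmarked against a known
truth.

## The model, stage by stage

### Preprocessing

* **Background subtraction** clamps `max(value - offset, 0)` per sample;
  missing cells stay missing ("not detected") and are excluded from means
  and tests rather than imputed as zero.
* **Detection** keeps a feature in a `(species, source)` stratum when its
  mean background-subtracted intensity across the stratum's samples is
  *strictly above* 300. We read "above 300" literally; the boundary (a
  constant row at exactly 300) is excluded and tested. Detection runs
  before normalization, matching the published order of operations.
* **U6 normalization** rescales every array so the U6 snRNA probe equals
  the across-array geometric mean of U6. Anchoring to the geometric mean
  (rather than to an arbitrary first sample) makes the result invariant to
  sample order, and the operation is idempotent to 1e-12 relative.
* **mRNA prefilter** reproduces the Illumina BeadStudio screen:
  p < 0.05, |Diff score| > 20, average signal > 100 (all strict). When
  only p-values are available, `diff_score_from_p()` supplies the
  manufacturer convention `-10 * sign(case - control) * log10(p)`, under
  which |score| = 20 corresponds to p = 0.01.

### Differential expression

Each stratum contrast produces one record per detected feature:

* **Fold change** is the ratio of linear group means, reported with the
  signed "negative reciprocal" convention: `r` when `r >= 1`, `-1/r`
  otherwise, so `|signed_fc| >= 1` always.
* **Testing** uses a two-tailed Welch (unequal-variance) t-test on log2
  intensities. Log2 stabilizes multiplicative array noise; the source
  analysis states only "two-tailed t-tests", and we prefer Welch because
  equal variances are not guaranteed across disease groups. If both
  groups are essentially constant the test is degenerate: equal means
  give p = 1 and unequal means give p = 0 (perfect separation), each
  flagged. One-way ANOVA with Fisher's LSD (`anova_lsd()`) is available
  as the multi-group alternative for three-cohort blood designs.
* **Replication** follows the per-subject rule: the fraction of case
  subjects whose individual ratio against the control-group mean lies
  strictly on the group's side of 1. "Replicated in at least 50% of
  subjects" is applied inclusively (`>= 0.5`). A ratio of exactly 1
  never replicates.
* **Filters**: significant (raw p < 0.05), magnitude (|fc| >= 1.5),
  replicated (fraction >= 0.5). No multiple-testing correction enters the
  filter — the published screen works on raw p-values — but a
  Benjamini–Hochberg column is emitted for information.

### Signature selection

* **Venn counts** are exact region counts over the per-source
  *significant* sets. The magnitude cut deliberately does not enter the
  Venn stage: the published intersection diagram counts "significant
  changes", and ±1.5-fold is applied later.
* **Cross-source**: a miRNA enters the rat signature when it passes all
  three flags in *every* one of the five sources with the same direction
  everywhere.
* **Cross-species**: a rat-signature miRNA is *concordant* when its
  direction matches the human T2D blood contrast and that human record is
  significant. The IFG fold change is recorded but never used for
  exclusion — pre-diabetic discordance (miR-30d and miR-182 flip in IFG)
  is biology worth reporting, not a rejection criterion. Probe-namespace
  differences (e.g. `miR-320` vs `miR-320a`) are reconciled by a
  user-supplied alias table; nothing is hard-coded.

### Targets and qPCR

* **Consensus voting**: a (miRNA, gene) prediction is accepted when at
  least 3 of the 5 supplied databases carry it. The package consumes
  static per-database tables and never queries the live services — the
  web databases have changed since the analysis pattern was published,
  and reproducibility requires frozen inputs.
* **Pair evaluation**: per condition, a pair is `inverse` when miRNA and
  mRNA signed fold changes strictly oppose (canonical repression),
  `concordant` when they strictly agree and both pass the magnitude cut
  (the proposed RNA-activator pattern for miR-30d/INS), `null`
  otherwise.
* **qPCR**: ΔCt is taken against the reference gene (18S rRNA by
  default), ΔΔCt is the case-minus-control difference of group-mean
  ΔCt, and the fold change is `E^-ΔΔCt` with efficiency fixed at 2
  unless overridden. The SEM is propagated from per-replicate ΔCt spread
  by the delta method (`sem = ln(E) * fc * sem_ΔΔCt`); the published
  tables state "mean ± SEM" without the propagation rule, so this choice
  is ours and is documented here. The raw ratio is retained everywhere;
  the signed convention is applied only at reporting, since published
  usage is itself inconsistent for ratios below 1.

### Reporting

Fold-change profiles (log2 ratios, profiles × features, `NA` for "not
detected") feed average-linkage hierarchical clustering on Euclidean
distances (UPGMA; missing values excluded pairwise) and a column-centered
PCA with a deterministic sign convention (the largest-magnitude loading of
each component is made positive). Dendrograms serialize to Newick with
branch lengths from merge heights. Heatmaps use the green
(down) / red (up) / grey (not detected) semantics.

## The synthetic-data generator

`generate_microarray_study()` emulates the study design the pipeline
expects:

| parameter | default | why |
|---|---|---|
| background miRNAs | 200 | roughly 200 miRNAs detectable per source |
| rat groups | 6 control + 6 case, 5 sources | six animals per diet group; pancreas, liver, adipose, skeletal muscle, blood |
| human cohort | 7 CTL / 6 IFG / 8 T2D | the first-batch blood cohort sizes |
| baseline log2 intensity | N(12, 1.5) | intensities in the thousands, comfortably above the 300 floor |
| noise_sd | 0.25 (log2) | typical array replicate noise; the benchmark condition |
| scale_sd | 0.2 (log2) | array-to-array scale effects, applied to every feature including U6, so normalization has exactly this to remove |
| U6 | 5000, jitter only | a stable normalizer probe |
| dropout | 10%, drawn as a low baseline ~2^6 | exercises the detection filter without deleting cells |

Planted magnitudes use the published per-tissue values where printed
(miR-144: pancreas 7.94, liver 4.26, adipose 4.34; miR-150: adipose 3.21,
liver 2.07; miR-146a: adipose −4.62; miR-30d: pancreas −2.81; miR-182:
skeletal muscle −4.23; human blood miR-144: T2D 3.07, IFG 1.385) and
2.5-fold elsewhere. In the IFG cohort miR-30d and miR-182 flip to
up-regulation and miR-144 shrinks, reproducing the reported pre-diabetic
discordance.

Two structural choices deserve a note:

* Intensities are log-normal (`log2 intensity = baseline + effect +
  jitter + N(0, noise_sd)`), the standard multiplicative microarray noise
  model; planted effects are exact shifts of the case-group mean, so the
  noiseless generator reproduces fold changes exactly.
* Planted signature baselines are drawn from the same baseline
  distribution *truncated above the detection floor* (default minimum
  log2 baseline 10, about four times the 300 threshold). The planted
  truth is *detectable* differential expression in every source — that is
  what defines a recoverable signature — so letting a "planted" miRNA
  fall below the detection filter in some tissue would contradict the
  truth table the generator emits. Background features are not truncated.

What the generator does **not** emulate: probe cross-hybridization,
intensity-dependent (loess-shaped) bias, correlated miRNA families,
batch-by-cohort confounding, or heavy-tailed outlier arrays. Passing the
recovery benchmarks therefore shows the pipeline's filters and
intersection logic are correct and calibrated under a clean noise model —
not that real deposits would yield the same lists.

## Numerical choices and degenerate inputs

* Detection, Diff score, and average-signal cuts are strict inequalities;
  the replication and magnitude cuts are inclusive ("at least").
* Welch p-values come from `stats::t.test`; degenerate variance is
  resolved as described above.
* Clustering ties are handled by `stats::hclust`; with continuous data
  ties have probability zero, and the brute-force UPGMA oracle in the
  test suite confirms topologies on random instances. Duplicate profiles
  merge at height 0.
* PCA drops features with any missing value (a complete matrix is
  required); requesting more components than the rank truncates with a
  warning. Explained-variance fractions sum to 1 with all components.
* Readers never coerce missing cells to zero, and all identifier matching
  is exact and case-sensitive.

## Problem sizes used by the shipped benchmarks

The test suite and the acceptance script run entirely on synthetic data at
desk scale: 20 seeded end-to-end pipeline runs for signature recovery
(each about 209 features × 81 samples), 100 random instances per
brute-force oracle comparison, 1000 null simulations for type-I
calibration, and 200 replicates of the Pearson estimator at n = 120 and
ρ = 0.78. These sizes were chosen as the smallest at which the binomial
and sampling error bands in the checks are meaningful.

## Known limitations

* The pipeline assumes the supplied sample sheet defines sensible strata;
  it will happily contrast n = 2 groups if asked.
* The GEO deposits behind the original analysis are not downloaded or
  parsed; the package consumes plain TSV matrices. Reproducing published
  accession-level counts is out of scope because the original filter
  settings are under-specified beyond what is implemented here.
* Efficiency-corrected qPCR models beyond a single global efficiency, and
  probe-level array summarization, are out of scope.
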