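# miRprog

Serum microRNA biomarker discovery for progression from at-risk
autoimmunity (CCP+/ACPA+ with musculoskeletal symptoms) to very early
rheumatoid arthritis (VERA), implemented as a tested, fully reproducible R
package. It reimplements a two-phase matched-cohort qPCR array analysis —
pilot screening of candidate miRNAs followed by validation against a
non-progressor comparator — together with a calibrated synthetic-cohort
generator, so the entire pipeline runs and is testable without any patient
data.

## The statistics at the core

Raw data are triplicate cycle-threshold (Ct) measurements per (sample,
miRNA) with "Undetermined" censoring at 40 cycles. The pipeline:

* **normalises** each sample against an endogenous control (RNU6B):
  dCt = mean(miRNA Ct) − mean(control Ct), after imputing undetermined
  wells at a detection ceiling (Ct 35) and excluding implausibly early
  amplification (Ct < 8), with sticky per-cell quality flags
  (imputed, low-expression Ct > 32, missing);
* computes **signed folds**: for an exponent x on the dCt scale,
  raw = 2^(−x), reported as raw if ≥ 1 else −1/raw, so folds never lie in
  (−1, 1). Within-patient fold change FC uses the median per-patient
  ddCt = dCt(follow-up) − dCt(baseline); between-group fold difference FD
  uses the difference of group median dCt, either raw or age-adjusted via
  median (quantile, τ = 0.5) regression with cohort medians reported at a
  reference age;
* **selects candidates** by |FD| or |FC| ≥ 4 plus ≥ 75 % direction
  consistency within progressors, with mean-fold rescue and
  newly-expressed detection as auxiliary panel routes, assembling a
  31-assay panel alongside a literature panel of nine RA-associated
  miRNAs;
* **evaluates** baseline dCt as a classifier of progression: rank/trapezoid
  AUROC with expression = −dCt, Youden-optimal sensitivity/specificity,
  stratified percentile-bootstrap 90 % CIs, and Spearman associations with
  clinical scores (substantive at |rho| > 0.3);
* **clusters** expression profiles by complete-linkage agglomeration with
  a canonical, permutation-invariant leaf order and exports the ordered
  heatmap matrix.

## Worked example

```r
library(miRprog)

sim <- simulateStudy(synthConfig(), seed = 7)   # study-shaped cohorts
res <- runPilot(sim$ct, sim$meta)
res$report
#> SelectionReport: 31 miRNAs evaluated, 12 on the panel
#> panel: miR-22, miR-382, miR-132, miR-146a, miR-155, miR-16, miR-18a, ...

res$fc[res$fc$mirna %in% c("miR-22", "miR-382", "miR-486-3p"),
       c("mirna", "ddct_median", "signed_value", "n_consistent")]
#>       mirna ddct_median signed_value n_consistent
#>      miR-22       -2.10         4.30           12
#>     miR-382       -1.97         3.91           12
#>  miR-486-3p       -2.02         4.05           12

val <- runValidation(sim$ct, sim$meta, pipelineConfig(),
                     panel = panel(res$report))
val$table2[val$table2$mirna == "miR-22",
           c("fd_baseline", "auc", "ci_low", "ci_high")]
#>  fd_baseline auc ci_low ci_high
#>           25   1      1       1
```

Reading this: the generator plants the three study-sized progression
effects (ddCt −2.1, −2.0, −2.0, i.e. ~4-fold upregulation at follow-up,
lower dCt = higher expression). With this seed the pilot recovers miR-22
(median FC 4.3, all 12 patients consistent) and miR-382 on the panel;
miR-486-3p's median FC of 4.05 clears the threshold here, but being planted
exactly at the 4-fold boundary it does so in only about two thirds of
seeds — an intrinsic property of a hard inclusive threshold, discussed in
the methods vignette. In validation, miR-22's large planted baseline
offset between progressors and non-progressors yields FD ≈ 25 and a
perfectly separating baseline classifier (AUC 1.0); null assays sit near
FD 1 and AUC 0.5.

The same stages are scriptable from a shell via
`inst/scripts/mirprog.R` (`simulate`, `pilot`, `validate` subcommands).

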