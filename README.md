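# ftdcascade

Biomarker cascade modelling in genetic frontotemporal dementia (FTD), with
white matter hyperintensity (WMH) burden as the biomarker of interest in
progranulin (*GRN*) mutation carriers.

In autosomal-dominant FTD, carriers of *C9orf72*, *GRN* or *MAPT* mutations
can be observed long before symptoms, and the order in which biomarkers
leave their normal range decides which markers are useful for early
detection and trial staging. This package is for researchers who want to
estimate that order from cross-sectional data and test directional
hypotheses on longitudinal data. It provides:

* **Normative WMH statistics** — ordinary least squares of
  `log10(WMH volume) ~ age + sex` on healthy controls; everyone's *adjusted*
  WMH is observed minus predicted. Group comparison across
  genotype-by-status cells and the eight lobes uses the tie-corrected
  Kruskal–Wallis *H*, Dunn's post hoc *z*, Bonferroni correction and
  Cliff's delta `δ = [#(a>b) − #(a<b)]/(n_a n_b)`.
* **A discriminative event-based model (DEBM)** — per biomarker, a
  constrained two-component Gaussian mixture of a normal and an abnormal
  state; per subject, posterior abnormality probabilities `P_ik`; a central
  event ordering `σ` minimizing the probability-weighted Kendall cost
  `Σ_i Σ_{(k,l) discordant} |P_ik − P_il|`; a bootstrap positional-variance
  diagram (B = 100, stratified by diagnosis); staging by maximizing
  `Σ_{j≤k} log P_σ(j) + Σ_{j>k} log(1 − P_σ(j))`; validation by stratified
  10-fold AUC and Spearman correlation with clinical scores.
* **Cross-lagged longitudinal regressions** — per directed biomarker pair,
  `Δresponse/Δt ~ predictor_baseline + age + sex + education + log NfL +
  response_baseline` on z-scored data, with one Benjamini–Hochberg family
  over all 48 models.
* **A synthetic cohort generator** with a known ground-truth cascade
  (latent stage per subject; event *j* of *K* fires when the stage exceeds
  `j/(K+1)`), used to validate every layer end to end.

## Worked example

```r
library(ftdcascade)

coh <- simulateCohort(cohortConfig(seed = 1))   # 763 subjects, 24 biomarkers
fit <- runDEBM(coh, bootstrap = 100, seed = 2)  # controls + GRN carriers (n = 480)
fit
#> DEBMFit
#>   admitted biomarkers: 8 of 9 screened
#>   ordering: wmh_total > wmh_temporal > ventricles > wmh_frontal > gm_temporal > nfl > cerebellum > gm_frontal
#>   staging AUC (10-fold CV): 0.999 +/- 0.003
```

Total WMH is placed first — lesion load becomes abnormal before
ventricular enlargement, NfL elevation and grey-matter atrophy — and the
continuous disease stage separates symptomatic carriers from controls
almost perfectly (AUC 0.999). One of the nine candidate biomarkers (here
GFAP, whose abnormal state is rare and heavily missing) failed the
carrier-vs-control screen and was excluded, mirroring how biomarker
admission works on real cohorts. The bootstrap positional-variance diagram
shows how certain each placement is (rows = biomarkers in the central
order, columns = positions, entries = placements out of 100):

```r
positionCounts(fit)
#>               1  2  3  4  5  6  7  8
#> wmh_total    98  2  0  0  0  0  0  0
#> wmh_temporal  0 54 31 14  0  1  0  0
#> ventricles    0 15 37 42  6  0  0  0
#> wmh_frontal   2 27 29 29  8  3  2  0
#> gm_temporal   0  0  0  8 37 35 17  3
#> nfl           0  2  3  7 34 35 17  2
#> cerebellum    0  0  0  0 15 18 30 37
#> gm_frontal    0  0  0  0  0  8 34 58
```

The directional longitudinal analysis recovers the generator's coupling —
baseline WMH predicts subcortical decline, never the reverse:

```r
long <- simulateLongitudinal(longitudinalConfig(seed = 3), coh)  # 83 GRN carriers
crossLagMatrix(long)
#> crossLagResultSet: 48 directed pair models, FDR threshold 0.05
#> significant associations:
#>  predictor    response         t        p_fdr
#>  wmh_total hippocampus -21.09085 1.334035e-28
#>  wmh_total    amygdala -21.51356 9.017999e-29
#>  wmh_total   cingulate -18.60313 7.479126e-26
```

`runFullAnalysis(runConfig(...))` chains all stages and writes CSV/JSON
artifacts plus a reproducibility manifest;
`inst/scripts/run-pipeline.R` is a thin command-line wrapper around it.

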