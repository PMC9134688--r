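# myelindex

Quantitative indices of developmental myelination in the neonatal rodent
brain, from diffusion MRI, ELISA and immunohistochemistry.

Early postnatal myelination can be accelerated experimentally (e.g. by
thyroid hormone), and detecting that acceleration *in vivo* requires
estimators that do not depend on observer-drawn, threshold-sensitive ROIs.
`myelindex` implements the full analysis chain for a two-group
(treated vs vehicle) developmental study:

* **Diffusion tensor estimation.** Per voxel, the single-tensor model
  `S_i = S0 · exp(−b_i · gᵢᵀ D gᵢ)` is fitted by ordinary least squares on
  log-signals; FA, MD, AD (= λ₁) and RD (= (λ₂+λ₃)/2) maps follow from the
  eigenvalues. NIfTI volumes with FSL-style `bvals`/`bvecs` in, NIfTI maps
  out.
* **Forebrain FA histogram analysis.** Normalized 0.01-bin FA histograms
  over one large forebrain ROI are fitted per subject with the
  three-parameter Burr XII distribution,
  `F(x) = 1 − (1 + (x/α)^c)^(−k)`; the fitted median
  `α(2^{1/k} − 1)^{1/c}` (and mode, mean) is a threshold-free index of
  global myelination, compared between groups with Welch's t-test.
* **Group statistics.** Student/Welch t-tests; the two-stage adaptive
  Benjamini–Krieger–Yekutieli FDR procedure at q = 0.1 for the ten-region
  white-matter comparisons; Fisher's exact test for eruption tables;
  two-way ANOVA (treatment × age) with Tukey post hocs; Pearson
  correlation of MBP against the FA median.
* **MBP quantification.** Four-parameter-logistic ELISA standard curves
  with back-quantification, LLOQ, spike-and-recovery and dilution
  linearity against the 70–120% acceptance band; IHC sections scored as
  percent MBP-positive hemisphere area after background subtraction and
  thresholding.
* **Synthetic data.** Two-group tensor phantoms with Rician noise,
  developmental MBP curves, ELISA plates, stained sections and eruption
  tables — all seeded and with known ground truth, so the whole pipeline
  runs end-to-end without animal data.

## Worked example

```r
library(myelindex)

## the study acquisition: 30 directions at b = 970 s/mm^2 plus one b0
sch <- makeScheme(30, 970)
sch
#> DiffusionScheme with 31 volumes
#>   b = 0 volumes: 1
#>   b = 970 s/mm^2: 30 directions

## FA of a prolate tract-like tensor (eigenvalues in mm^2/s)
computeFA(c(1.7e-3, 0.3e-3, 0.3e-3))
#> [1] 0.7990222

## Burr XII fit of a forebrain FA histogram (here: sampled values)
set.seed(1)
fit <- fitBurr(buildHistogram(rburr(5e4, 3, 1.5, 0.4), "pup01", "vehicle"))
fit
#> BurrFit: subject pup01 (vehicle)
#>   c = 2.985, k = 1.549, alpha = 0.4055 (sse 1.25e-05)
#>   mode 0.2861 | mean 0.3725 | median 0.3348

## tooth eruption, 9/11 treated vs 1/11 vehicle pups
fisherExact2x2(matrix(c(9, 2, 1, 10), 2, 2, byrow = TRUE))
#> [1] 0.001905216
```

The fitted median 0.3348 sits within 0.1% of the closed-form
`0.4·(2^{1/1.5} − 1)^{1/3} = 0.33499` of the sampled distribution, and the
eruption table reproduces the exact two-sided p = 0.0019.

A complete synthetic study — simulation, tensor fitting, histogram and
Burr analysis, regional FDR statistics, ELISA quantification, IHC scoring,
and the MBP–FA correlation — runs from one configuration:

```r
cfg <- studyConfig(outDir = "study1", seed = 1)
runFullStudy(cfg)
#> Synthetic myelination study -- study1
#>   FA shift (median): 0.2285 vs 0.1569, Welch p = 2.072e-09
#>   Regional discoveries: 31 of 40 tests
#>   MBP ANOVA treatment: F(1, 90) = 295.9, p = 3.394e-30
#>   MBP ~ FA median: r = 0.841 (r^2 = 0.706), p = 0.0006179, n = 12
#>   Teeth Fisher p = 0.001032
```

Here the treated group's radial diffusivity is reduced 25% in deep white
matter, which shifts the Burr-fit forebrain FA medians from ~0.157 to
~0.229 (Welch p ≈ 2e-09), is detected in the labelled tract regions after
FDR control, and couples positively (r = 0.84) with the plate-quantified
MBP of the same subjects. Every table and map is written under `outDir`,
and each stage can be re-run from the files alone (see
`?pipelineStages`); `inst/scripts/myelin-pipeline.R` exposes the stages as
shell subcommands.

## Package layout

| Area | Entry points |
|---|---|
| Scheme & phantom | `makeScheme`, `defaultPhantomSpec`, `simulateDWI` |
| Tensor fitting | `fitTensor`, `computeFA`, `computeScalarMaps`, `writeScalarMaps` |
| Histogram / Burr | `buildHistogram`, `fitBurr`, `compareGroups`, `dburr`/`pburr`/`qburr`/`rburr` |
| Statistics | `studentT`, `welchT`, `bkyFdr`, `fisherExact2x2`, `twoWayAnovaTukey`, `pearsonCorrelation`, `regionalMeans` |
| ELISA | `simulatePlate`, `fitStandardCurve`, `quantifySamples`, `spikeRecovery`, `dilutionLinearity` |
| IHC | `simulateIHCImage`, `percentPositiveArea` |
| Pipeline | `studyConfig`, `runFullStudy`, `stageSimulate` … `stageReport` |

The methods vignette (`vignettes/myelindex-methods.Rmd`) documents the
models, numerical choices and the generator's design in detail.
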