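---
title: "Quantifying developmental myelination: models and methods"
author: "myelindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying developmental myelination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelindex)
```

# Scope

`myelindex` quantifies developmental white-matter myelination in the
neonatal rodent brain from three complementary assays and ties them
together statistically:

1. **Diffusion tensor imaging (DTI).** Per-voxel tensors are estimated from
   multi-direction diffusion-weighted MRI; fractional anisotropy (FA), mean
   (MD), axial (AD) and radial (RD) diffusivity maps summarize
   microstructure. Myelination lowers radial diffusivity and raises FA.
2. **Forebrain FA histogram analysis.** Instead of thresholded manual ROIs,
   a single large forebrain ROI yields a normalized FA histogram per
   subject, fitted with the three-parameter Burr XII distribution; the
   fitted median (also mode and mean) is a threshold-free scalar index of
   global myelination, compared between groups with Welch's t-test.
3. **Protein-level readouts.** Myelin basic protein (MBP) concentration is
   back-quantified from ELISA plates through a four-parameter logistic
   standard curve with assay-acceptance checks, and MBP
   immunohistochemistry sections are scored as percent positively stained
   hemisphere area.

Regional comparisons use Student's t-test with two-stage adaptive FDR
control (Benjamini–Krieger–Yekutieli) at q = 0.1; developmental MBP series
use two-way ANOVA (treatment x age) with Tukey post hocs; tooth-eruption
tables use Fisher's exact test; and per-subject MBP is correlated with the
Burr-fit FA median (Pearson).

A synthetic-data module generates every input with known ground truth, so
the full pipeline runs and is validated without animal data.

# Tensor estimation

For direction $g_i$ at b-value $b_i$, the single-tensor model predicts
$S_i = S_0 \exp(-b_i\, g_i^\top D\, g_i)$. Taking logs gives a linear model
in $(D_{xx}, D_{yy}, D_{zz}, D_{xy}, D_{xz}, D_{yz}, \ln S_0)$, solved per
voxel by ordinary least squares — the default linear regression model of
mainstream DTI tools. Choices that matter:

* **Signal clamping.** Logs require positive signals; values at or below
  zero (possible in magnitude MRI noise troughs) are floored at the voxel's
  smallest positive signal times $10^{-3}$. Voxels with non-finite signals
  are excluded and masked out rather than guessed at.
* **Eigenvalues.** Whole-volume fits use the closed-form trigonometric
  eigenvalues of symmetric 3x3 matrices (vectorized over voxels, validated
  against `eigen()` in the tests); the single-voxel path returns the full
  eigensystem. Eigenvalues are sorted descending: AD = $\lambda_1$,
  RD = $(\lambda_2 + \lambda_3)/2$, MD = their combination $(AD + 2RD)/3$.
* **FA clamping.** Noise can push small eigenvalues negative. Negative
  eigenvalues are clamped to zero *only* for FA (keeping FA in $[0,1]$);
  AD/RD/MD use the raw values so diffusivities are not biased upward.
  All-zero eigenvalues give FA = 0 by convention.
* **Plain OLS.** No weighted least squares, RESTORE, or positivity
  constraints; the estimator is the stated linear model, kept exact and
  fast. Noiseless round trips recover tensors to ~1e-14 relative error
  (asserted in the tests).

The acquisition scheme mirrors the study: 30 diffusion directions at
b = 970 s/mm² plus one b = 0 volume. Directions come from a deterministic
Fibonacci spiral (no randomized electrostatic optimization, so schemes are
bit-reproducible). The polar spacing uses $z_i = 1 - 2(i+0.5)/(n+0.5)$: the
slight asymmetry removes an exact quadratic-form degeneracy of the
symmetric spiral at small even $n$ that would make a 6-direction scheme
rank-deficient; identifiability (design rank 7) is enforced at `designMatrix()`.

# FA histograms and the Burr XII fit

Histograms use 100 fixed bins of width 0.01 on $[0,1]$ (left-closed,
right-open, last bin closed at 1), normalized to sum to one, built without
any FA thresholding. Out-of-range values are dropped; NA values are an
error because they indicate an unmasked fit failure upstream.

The Burr XII distribution
$F(x) = 1 - \left(1 + (x/\alpha)^c\right)^{-k}$ with shapes $c, k > 0$ and
scale $\alpha > 0$ is fitted per subject by least squares on bin
probabilities. Numerical choices:

* **Objective: conditional bin probabilities.** The model probability of
  bin $[l, h)$ is $(F(h) - F(l))/F(1)$, i.e. the Burr CDF increment
  conditioned on the $[0,1]$ support. FA is bounded and the histogram is
  normalized over $[0,1]$, so conditioning matches the data normalization
  exactly: a histogram built from exact Burr bin probabilities is recovered
  to machine precision, whereas unconditioned increments leave a tail-mass
  mismatch that biases parameters at the ~1e-4 level. For realistic FA
  fits $F(1) \approx 1$ and the two objectives are indistinguishable.
* **CDF differences, not midpoint densities.** Bin probabilities are exact
  CDF increments, avoiding the coarse-bin error of pdf-times-width.
* **Initialization and optimizer.** The scale starts at the empirical
  histogram median; shapes on the grid $c \in \{1,2,4,8\}$,
  $k \in \{0.5,1,2,4\}$. The best grid start is refined by bounded
  Levenberg–Marquardt (`minpack.lm::nls.lm`, ftol 1e-10, at most 500
  iterations) — the least-squares structure makes LM both faster and far
  more accurate here than generic quasi-Newton, which stalls well short of
  the optimum on this objective.
* **Degenerate inputs.** All mass in one bin is rejected; non-convergence
  is flagged and descriptors are reported as `NA`, never silently numeric.
* **Descriptors.** Mode, mean and median come from the closed forms of the
  *unconditioned* fitted distribution: median
  $\alpha(2^{1/k}-1)^{1/c}$; mode $\alpha((c-1)/(kc+1))^{1/c}$ for $c>1$
  (else 0); mean $\alpha\,k\,B(k - 1/c,\, 1 + 1/c)$, reported only when
  $ck > 1$ and `NA` otherwise — a heavy-tailed fit never yields a
  fabricated mean.

Group comparison uses Welch's t-test on one descriptor (median by default,
matching the primary analysis); group-average histograms are the
arithmetic mean of subject bin heights, renormalized.

# Regional statistics and FDR

Regional means pool bilateral voxels per labelled structure (the ten
structures: fmi, gcc, bcc, scc, fmj, ec, aca, ic, opt, cp) and are compared
between groups per metric with Student's t-test. Multiplicity is handled by
the two-stage adaptive linear step-up procedure: stage 1 runs
Benjamini–Hochberg at $q' = q/(1+q)$ to estimate the number of true nulls
from the rejection count $r_1$; stage 2 reruns BH at $q' m/(m - r_1)$
(none rejected if $r_1 = 0$, all if $r_1 = m$). Reported q-values are the
smallest nominal level at which each test is rejected, found by bisection;
because the procedure is adaptive, a q-value may legitimately fall below
its raw p-value. Each diffusion metric (FA, RD, AD, MD) forms its own
10-region family at q = 0.1, the way separate analyses are run in
point-and-click statistics packages; the IHC per-day comparisons form
another family. No installed package implements this two-stage procedure,
so it is implemented here and checked in the tests against an independent
transcription of the rule and a 5,000-replicate null simulation of its FDR.

Fisher's exact test uses the probability-mass two-sided rule (sum of
hypergeometric probabilities not exceeding the observed table's) via
`stats::fisher.test`; the tests cross-check it against full enumeration.
Two-way ANOVA uses type-II sums of squares (`car::Anova` on `aov`) with
Tukey HSD on all treatment x age cells; treatment-within-age pairs are
flagged since those are the comparisons of interest. The developmental IHC
data get both treatments — per-day t-tests with FDR control and
ANOVA + Tukey — because both are legitimate and answer slightly different
questions; neither is privileged.

# ELISA quantification

Standard curves use the four-parameter logistic
$f(x) = U + (L - U)/(1 + (x/C)^B)$ on blank-subtracted signals — the
immunoassay default for sigmoidal direct-detection curves. The fit is
least squares with an analytic Jacobian (a finite-difference Jacobian
floors the attainable accuracy near 1e-8 relative; the analytic one reaches
machine precision on noiseless plates). Monotonicity of signal in
concentration is checked up front and non-monotone plates are rejected.

* **LLOQ rule.** The lower limit of quantification is the lowest nonzero
  standard whose back-calculated concentration recovers its nominal value
  within 70–120% — the assay's own acceptance band, reused because no
  other rule is specified for the assay.
* **Back-quantification.** Sample signals are inverted through the fitted
  curve and scaled by their dilution factor. Signals at or above the upper
  asymptote are flagged saturated; concentrations below the LLOQ are
  flagged, not extrapolated.
* **Acceptance checks.** Spike recovery is
  $(\text{spiked} - \text{base})/\text{nominal} \times 100$ and dilution
  linearity is each step's neat estimate relative to the least-diluted
  reference; both pass in $[70, 120]\%$.

# IHC area fraction

After absolute-value background subtraction, pixels inside the hemisphere
mask with $|I - I_{bg}|$ above a threshold count as MBP-positive; the score
is the percentage of mask pixels positive. The threshold is a parameter
(the original instrument setting is not recoverable); the default when none
is given is the midpoint between the background and foreground intensity
modes of the masked image (two-cluster k-means seeded at the intensity
extremes). The score is non-increasing in the threshold, which the tests
assert as a property.

# The synthetic-data generator

The generator defines the study conditions under which everything is
validated; its defaults are fixed once and mirror the study design where
stated (two groups of n = 6 DTI subjects, 30-direction b = 970 scheme,
0.01 histogram bins, q = 0.1, 70–120% acceptance band, 11 + 11 pups in the
eruption table), with the remaining magnitudes chosen at realistic values
for a PND10 rat pup and documented here.

* **Phantom.** A 16 x 16 x 6 voxel slab: ten 3 x 3 x 2 prolate tract boxes
  (axial 1.4e-3, vehicle radial 0.6e-3 mm²/s, FA ≈ 0.49) carrying the ten
  regional labels, embedded in weakly anisotropic parenchyma (axial 1.0e-3,
  vehicle radial 0.8e-3, FA ≈ 0.13) that forms the bulk of the forebrain
  ROI, with an isotropic fluid-like rim (2.0e-3 mm²/s) outside. The
  treated group's radial diffusivity drops by `rdReduction` (default 25%)
  in tracts and half that in parenchyma. The parenchyma compartment is
  essential, not decorative: an isotropic background would make the
  forebrain histogram a two-point mixture whose Burr median is pinned to
  the noise-FA peak and blind to the tract effect, whereas the developing
  brain — and hence the observed whole-distribution shift — has low but
  nonzero anisotropy almost everywhere. Immature cortex at this age is
  itself anisotropic, so a brain-wide (if attenuated) treatment response is
  the realistic emulation.
* **Noise.** Rician on magnitude signals,
  $\sqrt{(S + n_1)^2 + n_2^2}$ with $n_j \sim N(0, S_0/\mathrm{SNR})$,
  the standard model for magnitude MRI; SNR defaults to 25 and infinite
  SNR returns the exact forward model, which underpins all round-trip
  tests. No acquisition details beyond direction count and b-value are
  available, so the SNR and direction table are stand-ins, not
  reconstructions.
* **MBP curve.** Mean MBP is logistic in age (baseline 0.5 ng/mL, plateau
  50 ng/mL, midpoint PND10, time scale 1.5 days) with the treated
  midpoint shifted 2 days earlier by default, so treated and vehicle
  curves separate most strongly at the late ages — the qualitative shape
  of the developmental data. Noise is multiplicative with CV 0.15, floored
  at zero.
* **Plate.** Standards form a 7-point 2-fold series from 100 ng/mL plus a
  blank (lowest standard 1.5625 ng/mL); signals come from a 4PL with
  multiplicative noise. Sample concentrations are in-well values; the
  pipeline's lysates are measured at 4-fold dilution so that plausible
  neat concentrations land mid-curve.
* **Sections.** Stained images place exactly
  `round(fraction x mask area)` foreground pixels inside an elliptical
  hemisphere mask, so the generator returns the realized fraction and the
  quantifier can be checked for exactness. Between-animal variability of
  the stained fraction (CV 0.15) makes the per-day statistics
  well-defined.
* **Determinism.** Every generator takes a seed and is bit-reproducible;
  the pipeline derives per-stage seeds from the master seed, and two runs
  with one seed produce byte-identical tables.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: EPI/eddy-current/motion artifacts, partial-volume
continua and anatomical geometry, spatial noise correlations, plate
position effects, or stain heterogeneity; the mapping from histology to a
binary foreground is idealized.

# The pipeline

`runFullStudy()` chains file-coupled stages (simulate, fit-dti, histogram,
regional-stats, mbp, correlate, report); each stage reads only the declared
artifacts of earlier stages, so any stage can be re-run in place, and a
thin command-line wrapper (`inst/scripts/myelin-pipeline.R`) exposes them
as subcommands. The correlation stage joins plate-quantified MBP of the
DTI-scanned subjects with their Burr-fit medians (inner join on subject,
mirroring the same-pup design).

Problem sizes used in the validation suite are deliberate package choices:
tensor round trips use 1,000 random SPD tensors, FA properties 10,000,
Burr sampling fits 5 x 10⁴ draws, FDR control 5,000 null replicates, and
the power/null and end-to-end checks 20 independent seeds each; at these
sizes every stochastic assertion has comfortable margin over its sampling
noise.

# Known limitations

* Log-linear OLS is the stated estimator but not the most efficient at low
  SNR; no WLS/RESTORE variants are provided.
* The Burr fit is least squares on binned data, not maximum likelihood on
  voxel values; with 100 bins and forebrain-sized ROIs the difference is
  negligible, but the objective is a documented choice, and the original
  study's fitting recipe is unstated.
* Tukey post hocs cover all cell pairs of the treatment x age design;
  families other than treatment-within-age are reported but usually
  uninteresting.
* The IHC threshold default is a heuristic; when instrument settings are
  known they should be passed explicitly.
* ELISA curve fitting assumes a monotone 4PL; plates with hook effects are
  rejected rather than modelled.
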