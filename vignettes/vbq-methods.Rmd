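---
title: "Voxel-based quantification: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based quantification: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbq)
```

This vignette documents the science inside **vbq**: the signal models and
estimators, the tissue-weighted smoothing that makes voxel-wise statistics on
quantitative maps meaningful, the statistical machinery, and the choices that
were genuinely open when the package was designed. It states no empirical
result that the package's tests and `scripts/acceptance.R` do not themselves
compute.

## 1. The problem

Voxel-based morphometry localises differences in tissue *volume*. Quantitative
MRI goes further: longitudinal relaxation rate R1 (s^-1), effective transverse
relaxation rate R2* (s^-1), magnetization-transfer (MT) saturation (p.u.) and
the signal amplitude (proportional to proton density) are physical tissue
properties sensitive to myelin, iron and water content. Voxel-based
quantification (VBQ) brings such maps into a common (standard) space and runs
voxel-wise group statistics on them — but ordinary Gaussian smoothing, the
workhorse of voxel-based analysis, *averages parameter values across tissue
boundaries*, which destroys exactly the quantitative interpretation the maps
were acquired for. The core of this package is a weighting/smoothing operation
that preserves quantitative values within a tissue class.

## 2. Signal model and map estimation

### 2.1 Multi-echo FLASH

Three spoiled gradient-echo (FLASH) acquisitions give predominant T1-, PD- and
MT-weighting through repetition time and flip angle (defaults: T1w 18.7 ms /
20°, PDw and MTw 23.7 ms / 6°, the MTw scan preceded by an off-resonance
saturation pulse). Echoes are read at six equidistant times from 2.2 ms to
14.7 ms, with two extra echoes (17.2, 19.7 ms) for the PD-weighted scan. Per
voxel,

$$ S(TE) = S_0\, e^{-TE \cdot R2^*}, $$

and, in the small-angle rational approximation of the spoiled steady state
with achieved flip angle $a = b_1 \alpha$ (radians) and repetition time $TR$
(seconds),

$$ S_0 = A\, a \frac{R_1 TR}{a^2/2 + R_1 TR + \delta}, $$

where $\delta$ (fractional; `MTsat`/100) is the per-TR saturation imposed by
the MT pulse and is zero for the T1w/PDw scans. The simulator can also use
the full Ernst equation (`model = "ernst"`); for the MT-weighted scan the
rational saturation form is retained, since a closed-form Ernst steady state
with a saturation pulse would require a two-pool model. In the regime the
protocol uses (flip ≤ 20°, $R_1 TR \le 0.05$) the two forms agree to about
1% (the worst case, ~1.02%, is the $R_1 \to 0$ limit at 20°).

The MT pulse is transmitted by the same coil as the excitation pulse, so its
achieved saturation scales with the square of the local transmit factor:
the simulator applies $\delta_{\mathrm{eff}} = \delta\, b_1^2$. This is what
makes the *estimated* MT saturation insensitive to transmit bias (see 2.3).

### 2.2 Estimators

`fit_r2star()` regresses $\log S$ on TE (seconds) per voxel — plain
unweighted OLS, matching the log-linear estimation the method prescribes —
over the eight PD-weighted echoes by default (an option pools all three
weightings). Echoes with non-positive signal are dropped per voxel; voxels
with fewer than three usable echoes are masked, never errors.

`estimate_r1_amplitude()` uses the dual-flip-angle forms that invert the
rational model exactly:

$$ R_1 = \tfrac12\,
   \frac{S_{T1}\alpha_{T1}/TR_{T1} - S_{PD}\alpha_{PD}/TR_{PD}}
        {S_{PD}/\alpha_{PD} - S_{T1}/\alpha_{T1}},\qquad
   A = S_{PD} S_{T1}\,
   \frac{TR_{PD}\alpha_{T1}/\alpha_{PD} - TR_{T1}\alpha_{PD}/\alpha_{T1}}
        {S_{T1} TR_{PD}\alpha_{T1} - S_{PD} TR_{T1}\alpha_{PD}}. $$

`compute_mtsat()` then solves the MT-weighted signal for the saturation:
$\delta = (A \alpha/S_{MT} - 1) R_1 TR - \alpha^2/2$, reported in p.u.
(×100). Negative values under noise are kept but counted in a QC summary.

Because the first six echo times are shared by all three weightings, echo
averaging multiplies every weighting's steady-state amplitude by the same
mean decay factor $\overline{e^{-TE\,R2^*}}$. That factor cancels inside the
R1 and MTsat estimators, but it biases the amplitude; `fit_parameter_maps()`
therefore divides the amplitude by the factor computed from the fitted R2*
(`decay_correct_amp = TRUE`), so the reported amplitude refers to TE = 0.

### 2.3 Transmit-bias correction

Substituting $a = b_1\alpha$ into the estimators shows (exactly, for the
rational model; to excellent approximation for the Ernst model) that the
apparent R1 equals $R_1 / b_1^2$ — a purely multiplicative spatial bias —
while MT saturation is unaffected once the saturation pulse's own $b_1^2$
scaling is accounted for. `correct_r1_bias()` supports:

* **analytic**: with a measured B1 map, divide out the $1/b_1^2$ field;
* **estimation** (a simplified unified-segmentation-free analogue of
  information-based correction): fit a low-order 3-D polynomial (default
  total degree 3) to log apparent R1 over high-probability (≥ 0.9) GM/WM
  voxels with per-tissue intercepts, i.e. minimise intra-tissue log-variance;
  normalise the field to unit geometric mean and divide it out. The
  polynomial degree bounds the spatial frequency of what can be removed; the
  degree-3 default matches the low-order fields coil physics produces.

## 3. Spatial normalisation and tissue-weighted smoothing

A deformation $\varphi$ maps standard-space coordinates to native space
(displacements stored in mm on the standard grid; voxel index 0 sits at the
world origin, `mm = (index-1) * voxel size` — stated explicitly because
NIfTI conventions differ between tools). Warping is pull-back resampling
`vol(phi(x))` with nearest/trilinear/cubic interpolation (trilinear default;
the interpolation order is not dictated by the method). `jacobian_determinant()`
uses central differences (one-sided at borders), so the identity field gives
exactly 1.

Tissue weights combine volume change and partial volume:
$w = |D\varphi|\; t(\varphi)$, with $t$ the tissue probability. The VBQ
smoothing of a parameter map $s$ in standard space is

$$ \tilde s = \frac{g * (w\, s)}{g * w}, $$

one and the same truncated, unit-sum Gaussian kernel $g$ (FWHM 6 mm default;
$\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$, truncated at $4\sigma$) applied with
zero padding to numerator and denominator. Three consequences, all enforced
as tests:

* a constant map is reproduced exactly wherever the smoothed weight is
  positive (the ratio self-renormalises, including at borders — the reason
  zero padding rather than reflection is used);
* *no bleeding*: values at voxels with zero weight cannot influence the
  output, whatever their magnitude;
* the output at a valid voxel is a convex combination of input values on the
  weight support (range preservation).

Voxels where $g*w$ falls below $10^{-6}$ of its maximum are masked invalid
rather than divided. For morphometry, `modulate_and_smooth()` computes
$g * (t(\varphi)\,|D\varphi|)$ — tissue volume density.

The kernel is applied on the standard grid. An alternative reading of the
procedure defines the kernel in native millimetres (the deformation would
then reshape it); with the smooth, small-amplitude deformations the phantom
generates the difference is second-order, and the standard-grid convention
keeps the preservation identities exact.

## 4. Group statistics

### 4.1 Masks and design

Analysis masks average the warped GM/WM probabilities across subjects,
threshold at 0.2 and assign each voxel exclusively to the tissue with the
higher mean (ties excluded) — an operationalisation of "exclusive"
mask construction; the masks are disjoint by construction. The design per
parameter has intercept, age, gender (±1/2) and total intracranial volume,
non-intercept columns mean-centred (coding chosen so the intercept is the
cohort mean; the method source does not state a coding). The per-parameter
blocks are concatenated into one block-diagonal design; because the blocks
share no columns, the concatenated OLS betas are *identical* to separate
per-parameter fits (tested to 1e-10), while residual variance is estimated
per block — the package's realisation of block-wise variance components
(full ReML covariance pooling is out of scope; with disjoint blocks it would
not change the betas, which is the property the design exists to preserve).

### 4.2 Inference

Two-tailed voxel T statistics with per-voxel OLS variance; family-wise error
control by either

* **Bonferroni** over the mask (default), or
* **max-|T| permutation** (≥ 100 permutations enforced, 1000 default): the
  age regressor is residualised against the nuisance columns, permuted, and
  re-orthogonalised against the nuisance space before computing statistics
  on the nuisance-residualised data. Skipping that re-orthogonalisation
  deflates the permutation null and inflates the FWER — measurably so at
  n = 26 — which is why the projection step is part of the algorithm.
  Permutation p-values use the (1 + count)/(B + 1) convention.

Random-field-theory correction is deliberately not implemented: it requires
smoothness estimation machinery orthogonal to this package's contribution,
and the permutation test is exact under exchangeability. An auxiliary
uncorrected threshold (p < 0.001) flags trends; peak tables report local
maxima of |T| over 18-connectivity with world coordinates, equivalent z, and
corrected/uncorrected p. `overlap_labels()` binarises each parameter's map
by direction at the trend threshold and labels every distinct combination —
the "which parameters change together where" summary map.

### 4.3 Multivariate eigenvariates

`mlm_age_eigen()` standardises each voxel across subjects, residualises
against the nuisance regressors, forms the voxels × parameters matrix of
fitted age effects, and decomposes it by SVD: each component is a spatial
map, a unit parameter-loading vector, and a variance-explained fraction
(fractions sum to 1). Standardisation (rather than raw scale) is used so
that parameters with different units contribute comparably; loadings are
therefore on the standardised scale.

Significance per component uses a Lawley–Hotelling trace statistic with its
F approximation (exact Hotelling T² for a single tested regressor) — but on
**split samples**: patterns are estimated on half the subjects and the trace
test is evaluated on the held-out half's component scores. Projecting the
same subjects' data onto eigenvariates estimated from them inflates the
statistic enormously (the leading singular vector is selected to maximise
exactly the tested association); the split keeps the null rejection rate at
the nominal level, which the test suite verifies by simulation. The cost is
power at small n; the maps and loadings themselves always use all subjects.

## 5. The synthetic phantom

The generator produces everything the pipeline consumes, so the whole chain
is testable without acquired data:

* **geometry**: nested ellipsoids (WM core, GM shell, CSF rim, air outside)
  with a logistic partial-volume edge. The edge scale default (0.4 voxels,
  i.e. a 10–90% transition under two voxels) matches point-spread-limited
  segmentation sharpness; per-subject jitter (±2% radii/centre) creates
  anatomical variability and, through it, TIV variation.
* **ground truth**: probability-weighted mixtures of literature-typical 3T
  values (R1 0.77/1.10/0.25 s^-1, R2* 18/21/1.5 s^-1, MTsat 2/4/0 p.u.,
  amplitude 800/720/950 a.u. for GM/WM/CSF), an optional smooth within-tissue
  variation, and a low-order polynomial B1 field (default range 0.95–1.05
  across a cohort; 0.8–1.2 in bias-correction stress tests).
* **deformations**: white noise smoothed at a quarter of the field of view,
  scaled to a maximum displacement (1 mm default per subject), attenuated
  until the Jacobian determinant is positive everywhere; amplitude 0 is the
  exact identity.
* **cohort**: n = 26, ages uniform on [18, 85], 19 of 26 male — the study
  design the statistics address. The default age effect is MT saturation
  declining by 0.05 p.u. per year uniformly across the white-matter class
  (applied inside the region indicator, tissue probability ≥ 0.5), with the
  other parameters null. Truth-level voxel noise (0.05 p.u. MTsat, 0.01 s^-1
  R1, 0.3 s^-1 R2*, 4 a.u. amplitude) and echo noise (SD 0.5, signal
  amplitudes ~65) are deliberately modest: they put single-voxel theoretical
  power near 1, so recovery failures indicate pipeline defects, not chance.
  A slope of 0.05 p.u./year is larger than typical in-vivo ageing effects —
  it is sized for near-certain detection in a single simulated cohort.
* noise is additive Gaussian, not Rician: at the simulated SNRs the
  difference is negligible and Gaussian keeps estimator-bias analysis clean.

Cohort simulations for the group-level checks run on a 24³ grid with 2 mm
voxels. The phantom is a miniature head: what matters for the smoothing
analysis is the ratio of structure size to kernel width, and 2 mm voxels put
the WM core at about five kernel FWHMs across, comparable to real deep white
matter under a 6 mm kernel. (At 1 mm voxels the same phantom puts most of
the WM within one kernel radius of a boundary and the recovered slopes are
visibly diluted — a real property of kernel-scale objects, not a pipeline
defect; the package's own attenuation analysis reproduces it exactly as
$g*(wM)/g*(w)$.)

What the phantom does **not** emulate: acquisition artefacts (parallel
imaging, partial Fourier), motion, k-space effects, WM hyperintensity
lesions, Rician noise floors, and real registration error (deformations are
generated, not estimated). Passing tests therefore demonstrate correctness
of the estimators and pipeline algebra under the stated models — not
robustness to everything real data does.

## 6. Numerical choices and degenerate inputs

* FWHM→σ: $\sigma = \mathrm{FWHM}/\sqrt{8\ln2}$; truncation at 4σ with
  renormalisation to unit sum.
* Denominator floors: dual-angle estimator denominators below 1e-6 of their
  robust (99th percentile) maximum are masked, not zero-filled; the R2* fit
  masks voxels with < 3 positive echoes; MTsat masks non-positive MT signal.
  Validity masks propagate through warping (NA) and into the group mask
  (voxels must be valid in every subject).
* The smoothed-weight floor is 1e-6 × max(g*w).
* `fwhm = 0`, identity deformations, unit Jacobians, degenerate B1 ranges
  are all exact fixed points, asserted in tests.
* All randomness flows through explicit seeds (`withr::with_seed`); equal
  seeds give bit-identical phantoms, cohorts and statistical outputs.

## 7. Problem sizes used by the test suite

Unit tests use 10³–20³ grids. The acceptance-style checks use: 24³ grids for
the smoothing property sweeps (20 random weight/kernel draws); 16³ for the
dense-convolution oracle; 200 replicates × 1000 voxels × 1000 permutations
for FWER calibration; one 26-subject cohort run plus 50 replicate cohorts
for effect recovery and null-parameter specificity; 200 replicates for the
multivariate null calibration. These sizes make the full suite run in
minutes while keeping every Monte-Carlo bound inside its stated tolerance.

## 8. Known limitations

* The estimation-mode bias correction removes only fields representable by
  the polynomial basis and cannot recover the global scale (by design: the
  field is normalised to unit geometric mean).
* Per-block variance estimation ignores error correlations between
  parameters within a subject; betas are unaffected, but cross-parameter
  contrasts (not implemented) would need the full covariance.
* The split-sample trace test trades power for calibration at n = 26.
* Peak tables do not attempt anatomical labelling, and no cluster-extent
  inference is provided (voxel-level FWE only).
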