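# vbq — voxel-based quantification of multi-parameter MRI maps

Quantitative MRI turns signal intensities into physical tissue parameters:
the longitudinal relaxation rate **R1** (s⁻¹), the effective transverse
relaxation rate **R2\*** (s⁻¹), the semi-quantitative **MT saturation**
(p.u., the percentage loss of longitudinal magnetization per off-resonance
pulse — a myelin-sensitive index) and the **signal amplitude** (∝ proton
density). `vbq` implements the full analysis chain for voxel-wise group
studies of such maps, for imaging scientists who want the method available
as tested, scriptable R:

1. **Map estimation** from three multi-echo FLASH acquisitions (T1-, PD- and
   MT-weighted): echo averaging, log-linear R2\* fitting, the dual-flip-angle
   rational estimators

   R1 = ½ · (S_T1 α_T1/TR_T1 − S_PD α_PD/TR_PD) / (S_PD/α_PD − S_T1/α_T1),
   δ = (A α/S_MT − 1) · R1 · TR − α²/2,

   and transmit-bias (B1) correction of R1 — analytic when a B1 map exists
   (apparent R1 = R1/b1²), otherwise estimated as a smooth log-domain
   polynomial field minimising intra-tissue variance.
2. **Spatial normalisation that keeps values quantitative**: pull-back
   warping, Jacobian determinants |Dφ|, tissue weights w = |Dφ|·t(φ), and
   the tissue-weighted smoothing **g\*(w·s) / g\*(w)** — a kernel-weighted
   within-tissue average that reproduces constants exactly, never bleeds
   values across tissue boundaries, and preserves the input range. Jacobian
   modulation + smoothing for tissue-volume (VBM-style) maps.
3. **Group statistics**: exclusive GM/WM masks (mean probability ≥ 0.2,
   higher tissue wins), a block-diagonal multi-parameter GLM (age, gender,
   total intracranial volume; betas identical to separate fits), two-tailed
   T maps, family-wise-error control by Bonferroni or max-|T| permutation,
   overlap label maps of parameter×direction combinations, and a
   multivariate eigenvariate analysis of age effects (SVD of the
   standardised, nuisance-residualised age-effect matrix with split-sample
   Lawley–Hotelling inference).
4. A **synthetic phantom generator** (tissue geometry, ground-truth maps,
   FLASH signals, B1 fields, deformations, ageing cohorts) so the entire
   pipeline is testable end-to-end without any acquired data.

See `vignettes/vbq-methods.Rmd` for the models, assumptions and design
decisions.

## Worked example

Simulate a 26-subject ageing cohort (ages uniform 18–85, 19 male) in which
white-matter MT saturation declines by 0.05 p.u. per year while R1 and R2\*
carry no age effect, then run the full pipeline:

```r
library(vbq)
library(generics)   # tidy(), glance()

template <- make_tissue_phantom(c(24, 24, 24), voxel_size_mm = c(2, 2, 2),
                                seed = 99, jitter = 0)
cohort <- make_cohort(cohort_spec(seed = 11), template)
res <- analyze_cohort(cohort, run_config(seed = 11))

res$fit
#> <vbq_glm> 3 parameter block(s), n = 26, dof = 22, 2257 voxels

tidy(res$fit)
#> # A tibble: 12 × 6
#>    parameter term        estimate        sd       min       max
#>  1 mtsat     intercept  3.79      0.167      3.46      4.00
#>  2 mtsat     age       -0.0462    0.00354   -0.0502   -0.0381
#>  6 r1        age        0.0000309 0.0000853 -0.000315  0.000242
#> 10 r2s       age        0.000179  0.00121   -0.00378   0.00394
#> # ... (intercept/gender/tiv rows omitted here)

sum(res$fwe$mtsat$fwe)          # FWE-significant voxels for MT saturation
#> [1] 2257                      # the whole WM mask lights up ...
sum(res$fwe$r1$fwe)             # ... and the null parameter stays clean
#> [1] 0

head(res$fwe$mtsat$peaks, 3)
#> # A tibble: 3 × 8
#>   parameter  x_mm  y_mm  z_mm     t     z    p_unc    p_fwe
#> 1 mtsat        18    20    24 -736. -14.8 8.30e-50 1.87e-46
#> 2 mtsat        26    22    18 -676. -14.7 5.47e-49 1.23e-45
#> 3 mtsat        20    24    24 -657. -14.7 1.01e-48 2.29e-45

glance(res$mlm)
#> # A tibble: 1 × 5
#>   n_subjects n_parameters n_components var_frac_1      p_1
#> 1         26            3            3      0.911 1.26e-15
```

Reading the numbers: the estimated MT-saturation age slope averages
−0.0462 p.u./year against a true −0.05 (the remaining ~7% attenuation is
the deterministic partial-volume dilution of kernel-scale objects, which the
package can reproduce exactly as g\*(w·M)/g\*(w)); every WM voxel is
FWE-significant for MT while the null parameters produce no detections; and
the first multivariate component — MT-dominated, as injected — explains 91%
of the age-effect variance at p ≈ 1e-15. The extreme T scores reflect the
deliberately low simulation noise (single-voxel power ≈ 1).

A cohort can also be written to disk as NIfTI + TSV + JSON
(`write_cohort()`), analysed from disk (`run_pipeline(run_config(...))`),
or driven from a shell via the thin CLI in `inst/cli/vbq`
(`vbq phantom | fit-maps | smooth | vbm-prep | glm | mlm | run`).

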