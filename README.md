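# petref

Data-driven reference-region optimization for dynamic tau-PET.

## The problem

Semiquantitative tau-PET readouts (SUVr, VTr) scale the signal in a
pathology-bearing target region by the signal in a reference region assumed
free of specific binding. For 4-repeat (4R) tauopathies such as progressive
supranuclear palsy (PSP), the conventional inferior cerebellar grey-matter
reference is itself at risk of 4R tau contamination (dentate nucleus,
peri-cortical oligodendroglial tau), which shrinks patient-vs-control
differences and can mask clinical associations. `petref` implements a
pipeline that side-steps the problem:

1. **IDIF extraction** — an image-derived input function is pulled from the
   carotid signal of the dynamic scan itself (spatial ICA over early frames,
   carotid-template component selection, segment masking, erosion, per-frame
   maximum), so no tissue reference is needed for quantification.
2. **Logan VT mapping** — voxel-wise graphical analysis: for frames with
   midpoint ≥ t*, the slope of ∫C_T/C_T(T) against ∫Cp/C_T(T) estimates the
   total distribution volume VT.
3. **Reference search** — every candidate white-matter region (eroded 2 mm
   to dodge grey-matter spill-in) is used in turn to normalize the VT maps;
   an ANCOVA (age- and sex-adjusted) scores the patient-vs-control
   separation of the target-region VTr; candidates surviving family-wise
   error correction (Bonferroni, p < 0.05) are merged into one optimized
   reference mask.
4. **Validation statistics** — SUVr (static 20–40 min window) and VTr under
   the searched and the conventional reference are compared via ANCOVA with
   Tukey-adjusted pairwise tests and Cohen's d, ROC analysis with paired
   DeLong AUC comparison, covariate-adjusted severity regression, and a
   permutation-based voxel-wise cluster test.

Because suitable patient data are not publicly available, the package ships
a synthetic dynamic-PET phantom generator (`phantom_spec()`,
`simulate_cohort()`) with full kinetic ground truth — a tri-exponential
bolus input, one-tissue-compartment tissue curves (VT = K1/k2), a
carotid-like tube with partial-volume profile, group-dependent VT
elevations, reference-region contamination, covariates and
frame-duration-dependent noise — so every stage is testable end to end.

## Worked example

```r
library(petref)

spec <- phantom_spec(grid_dim = c(32L, 32L, 22L),
                     group_sizes = c(`PSP-RS` = 12L, HC = 12L))
vc   <- simulate_vt_cohort(spec, seed = 7)        # ground-truth VT maps
rep  <- search_reference(vc$vt_maps, vc$atlas, "pallidum", vc$subjects)
print(rep)

refs <- list(wm_ref    = rep$merged_mask,
             cereb_ref = atlas_mask(vc$atlas, "inferior_cerebellum"))
ro   <- cohort_readouts(vc, vc$atlas, refs, targets = "pallidum",
                        measures = "vtr")
lab  <- ro$group == "PSP-RS"
dl   <- delong_compare(ro$pallidum_vtr_wm_ref, ro$pallidum_vtr_cereb_ref, lab)
cat(sprintf("AUC searched %.3f vs conventional %.3f, DeLong p = %.2g\n",
            dl$auc_a, dl$auc_b, dl$p))
```

Output from this exact script:

```
reference_search_report: 6/8 candidates selected (alpha = 0.05, bonferroni), status: ok
 candidate eroded_voxels       t         p     p_adj selected
      wm_5            32  7.8813 1.467e-07 1.174e-06     TRUE
      wm_1            32  7.0624 7.559e-07 6.048e-06     TRUE
      wm_3            32  6.8720 1.121e-06 8.969e-06     TRUE
      wm_2            32  6.3144 3.656e-06 2.925e-05     TRUE
      wm_6            32  6.2328 4.360e-06 3.488e-05     TRUE
      wm_4            32  6.0555 6.414e-06 5.131e-05     TRUE
      wm_7            32 -1.6556 1.134e-01 9.073e-01    FALSE
      wm_8            32 -0.5544 5.855e-01 1.000e+00    FALSE
AUC searched 0.993 vs conventional 0.403, DeLong p = 1.9e-06
```

Reading it: the six clean white-matter candidates are selected (large
positive t: the target VTr separates patients from controls when normalized
to them); the two candidates whose VT was contaminated with the same
proportional elevation as the target self-cancel (t ≈ 0) and are excluded.
Normalizing to the merged searched reference gives near-perfect
discrimination (AUC 0.99), while the contaminated cerebellar reference
destroys it (AUC ≈ chance), and the paired DeLong test confirms the
difference. The full dynamic pipeline (images → IDIF → Logan VT → search →
validation) is driven by `run_all(run_config(...))` or the `petref` CLI
(`inst/cli/petref run-all --seed 1 --out DIR`).

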