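# jqma — automated alignment, subdivision and morphometry of small-animal knee joints

`jqma` is an R package for 3D quantitative morphometric analysis (QMA) of
segmented microCT scans of small-animal knee joints. Joint metrics such as
joint space width are exquisitely sensitive to how the scan is oriented and
how the joint is split into medial and lateral compartments — steps that
are traditionally done by hand, take an expert operator hours per study,
and must be re-tuned for every animal model. `jqma` automates both steps
with a configuration that is independent of the animal's physical scale,
and provides the downstream metrics plus the reproducibility statistics
used to judge them.

The package is aimed at preclinical osteoarthritis researchers working with
rat- and rabbit-sized joints (the two presets), but the pipeline runs on
any segmented joint given four binary masks: femur, tibia, femoral
cartilage, tibial cartilage.

## Method in brief

1. **Alignment.** The tibial surface is parameterized on the sphere and
   expanded in spherical harmonics, the three coordinate functions as
   V(θ, φ) = Σₗ Σₘ c_l^m Y_l^m(θ, φ), with the coefficients fitted by
   least squares. Truncating at degree 5 gives the bone's *basic form*;
   principal component analysis of that form defines one rigid transform
   (smallest component → z, second-smallest → x, tibial centre of mass →
   origin) applied identically to all components, preserving their
   relative pose.
2. **Subdivision.** A topographic height map of the aligned plateau is
   collapsed to a 1D medial–lateral profile, cropped to the central half
   of the footprint, and analysed with 1D sublevel-set persistence. The
   minimum of the second-most-persistent pair — the valley between the
   intercondylar tubercles — is the watershed plane that splits every mask
   into medial and lateral volumes of interest.
3. **Joint QMA.** Centre-of-mass vector angles (α, β, γ); distance to
   first tibio-femoral contact χ and contact-area growth rate m under
   virtual loading; SPECTRA-style joint space metrics (JSW, JSW.min,
   JSW.max, JSV) from largest-inscribed-sphere local thickness.
4. **Reproducibility.** Two-way consistency ICC(C,k) with 95 % CIs,
   precision errors PE(SD)/PE(%CV), RMSE/NRMSE, and the standard
   qualitative ICC bands (> 0.75 excellent).

Because the validation animal scans are not redistributable, the package
ships a synthetic phantom generator (rat/rabbit scale presets, repeat-scan
repositioning jitter, surface roughness) with exact ground truth; the whole
test suite and the acceptance analysis run on phantoms.

## Worked example

```r
library(jqma)

# a rat-scale phantom joint, posed as if freshly scanned
spec <- phantom_spec("rat", spacing = 100,
                     pose = list(angles_deg = c(12, -18, 25),
                                 translation_um = c(250, -100, 400)))
ph <- make_phantom_joint(spec)
res <- process_joint(ph$joint)

res$alignment$transform
#> <rigid_transform> rotation 34.45 deg, translation (-132.5, 125.5, 782.8) um

# dividing plane (aligned frame); canonical truth maps over by the tibial COM
res$x_divide
#> [1] 213.1
ph$truth$x_star - ph$truth$tibia_com_canonical[1]
#> [1] 170.5

res$metrics[, c("side", "alpha", "gamma", "chi_mm", "m_mm2_mm", "jsw_um", "jsv_mm3")]
#>      side alpha gamma chi_mm m_mm2_mm jsw_um jsv_mm3
#> 1  medial 87.15 7.121    0.3    10.66   1154   14.11
#> 2 lateral 87.15 7.121    0.3    10.29   1162   14.01
```

The transform undoes the 12/−18/25-degree acquisition pose (a combined
rotation of ~34°) and recentres the tibial centre of mass at the origin;
the dividing plane lands within half a voxel of the phantom's true
intercondylar valley; χ matches the phantom's built-in cartilage clearance
(truth 0.34/0.31 mm medial/lateral, quantized to the 0.1 mm contact step),
and the joint space metrics are reported per compartment in physical
units.

Reproducibility across repeat scans, the pipeline's central claim:

```r
specs <- sample_phantom_population(6, "rat", spacing = 120, seed = 1)
joints <- list(); man <- NULL
for (i in seq_along(specs)) {
  reps <- make_repeat_scans(specs[[i]], n_repeats = 3, noise_amplitude = 40,
                            seed = 100 + i)
  for (r in seq_along(reps)) {
    joints <- c(joints, list(reps[[r]]$joint))
    man <- rbind(man, data.frame(sample_id = paste0("S", i),
                                 repeat_id = paste0("R", r)))
  }
}
run <- run_pipeline(man, joints = joints)
run$repro[run$repro$metric %in% c("alpha", "jsw_um_medial", "jsv_mm3_lateral"), ]
#>             metric   ICC Lower95 Upper95  PE_SD PE_pctCV classification
#> 1            alpha 0.991   0.964   0.999  0.134    0.154      excellent
#> 8    jsw_um_medial 0.913   0.633   0.987 18.738    1.576      excellent
#> 15 jsv_mm3_lateral 0.887   0.523   0.983  0.375    2.566      excellent
```

A command-line front-end is installed with the package
(`exec/jqma`): `jqma run --manifest scans.csv --out results/`,
`jqma align ...`, `jqma phantom ...`, `jqma repro ...`.

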