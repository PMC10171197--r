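# supervent

Super-voxel CT ventilation imaging: surrogate regional lung-function maps
from a **single exhale CT** and a lung mask.

## Why

Functional-avoidance radiotherapy planning and COPD assessment need maps of
regional lung ventilation. The reference modalities (SPECT/PET ventilation)
are slow, expensive and low-resolution; the established CT-based surrogates
(CTVI\_HU, CTVI\_Jac) need two breathing phases plus deformable image
registration (DIR), and inherit its errors. `supervent` implements
**CTVI_SVD**, a registration-free surrogate that exploits the empirical
coupling between local lung density and local ventilation, along with the
DIR comparators, a full evaluation suite, and a synthetic thorax phantom so
everything runs and is tested without patient data.

## The method

1. Resample to 2 mm isotropic, 5-voxel 3D median denoising.
2. Partition the lungs into super-voxels with spacing-aware 3D SLIC
   (K_init = 1500): voxels join the seed minimising
   `D = sqrt(d_c² + (d_s/S)² m²)` with `d_c` the HU difference, `d_s` the
   spatial distance (mm), `S` the seed interval and `m` an adaptively
   re-estimated compactness.
3. Convert HU to density, `ρ = (HU + 1000)/1000`, average per super-voxel
   (`D_mean`), and zero super-voxels with `D_mean > 0.6` (denser than
   −400 HU: consolidation/tumour, which cannot ventilate).
4. Interpolate the gated `D_mean` values from the super-voxel geometric
   centres to every lung voxel, per lung side, with normalised Gaussian
   distance weights `w_ij = exp(−(r_ij/r_mean)²)`, then smooth with a
   mask-renormalised 3D Gaussian.

Comparators from a supplied deformation field `u` (convention
`x′ = x + u(x)`, mm): `ctvi_hu()` computes
`−1000 (HU_ex(x) − HU_in(x′)) / (HU_ex(x)(HU_in(x′)+1000))` and
`ctvi_jac()` computes `det(I + ∇u) − 1`; `supervoxel_average()` produces
their super-voxel-smoothed variants and VI_SV from a reference image.
Evaluation: voxel-wise Spearman correlation, 66th-percentile high/low
function split, Dice overlap of the high/low regions (DSC_h, DSC_l), and a
K_init sweep with paired t-tests.

## Worked example

```r
library(supervent)

ph <- make_phantom(phantom_spec(seed = 7))     # synthetic thorax, 96³ @ 2 mm
vi <- run_ctvi_svd(ph$ct_ex, ph$lung_mask)     # CTVI_SVD, K_init = 1500
attr(vi, "log")$k_final
#> [1] 1262

evaluate_case(vi, ph$spect_like, ph$lung_mask, ph$lung_mask)
#>    spearman     dsc_h    dsc_l n_voxels
#> 1 0.5103082 0.5814076 0.784354    67072

jac <- ctvi_jac(ph$dvf, ph$lung_mask)          # DIR comparator
spearman_voxelwise(jac, ph$vent_truth, ph$lung_mask)
#> [1] 0.941714
```

The 1262 super-voxels partition the two phantom lungs; against the
SPECT-like reference (8 mm blur + 10% noise) the single-CT map reaches a
voxel-wise Spearman correlation of 0.51 with Dice overlaps of 0.58 (high-
functioning third) and 0.78 (low-functioning rest) — the regime reported
for clinical cohorts. Against the noise-free ventilation truth the same map
scores 0.90, and the Jacobian comparator, which gets the true deformation
field for free, 0.94.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/ctvi.R phantom --out-dir ph --shape 48 --spacing 4
Rscript inst/cli/ctvi.R svd --ct-ex ph/ct_ex.nii.gz \
    --lung-mask ph/lung_mask.nii.gz --out ph/ctvi_svd.nii.gz --spacing 4
Rscript inst/cli/ctvi.R eval --ctvi ph/ctvi_svd.nii.gz \
    --reference ph/spect_like.nii.gz --ct-mask ph/lung_mask.nii.gz \
    --ref-mask ph/lung_mask.nii.gz
```

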