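# RelaxAniso

Orientation-resolved quantitative MRI relaxometry and relaxation-anisotropy
mapping in R.

Quantitative MRI relaxation parameters — T1, T2, continuous-wave (CW) and
adiabatic rotating-frame relaxation times (T1ρ, T2ρ), and relaxation along a
fictitious field (RAFF2–4) — differ in how strongly they depend on the
orientation of ordered tissue relative to the main magnetic field B0. In
collagen-rich tissues such as articular cartilage and tendon, residual
dipolar coupling makes transverse-family relaxation times vary severalfold
with the fiber-to-field angle, peaking at the magic angle (54.7°, where
P2(cos θ) = (3cos²θ − 1)/2 vanishes). RelaxAniso is aimed at researchers
quantifying this effect: it implements the complete analysis chain for a
specimen physically rotated in the magnet and imaged with a multi-parameter
relaxometry protocol at each orientation.

The core statistic is the voxel-wise **Michelson relaxation anisotropy**
over the sampled orientations,

    A = (T_max − T_min) / (T_max + T_min),

computed from co-registered relaxation-time maps (A is scale-invariant and
algebraically identical whether computed on times or rates). The chain:

1. **Signal models** — 2-parameter monoexponential decay for MESE T2,
   CW-T1ρ and adiabatic T1ρ/T2ρ (pulse trains mapped to t = n·τp),
   magnitude inversion recovery |S0(1 − 2e^(−TI/T1))| for T1, and a joint
   4-parameter steady-state model for RAFF with and without inversion
   preparation.
2. **Fitting** — voxel-wise bounded Levenberg–Marquardt least squares after
   quadrature noise-floor subtraction (sqrt(S² − σ²), the first-order
   Rician bias correction), with foreground masking and per-voxel validity.
3. **Registration** — in-plane rigid co-registration of every orientation
   to the first, estimated once per orientation from the first MESE echo
   (coarse rotation search + phase correlation, then continuous NCC
   refinement) and applied to all of that orientation's maps.
4. **Anisotropy** — voxel-wise A maps and per-ROI summaries (mean ± SD of
   voxel-wise A, plus the Michelson contrast of ROI-mean times), and a
   cross-sample report table in percent.
5. **Synthetic phantom** — a layered rotating phantom with depth-dependent
   fiber angles (superficial/transitional/radial cartilage zones, bone,
   an isotropic reference disc), dipolar relaxation
   R2(θ) = R2_iso + s·R2_aniso·P2(cos θ)², Lorentzian spin-lock dispersion
   of the anisotropic term, orientation-independent T1/adiabatic-T1ρ, and
   Rician noise — so the whole pipeline is testable without scanner data.

Data exchange uses NIfTI-1 volumes with JSON sidecars (RNifti/jsonlite).

## Worked example

Simulate the default cartilage-like phantom (five orientations 0–120°,
SNR 50), fit T2 maps, co-register, and quantify anisotropy:

```r
library(RelaxAniso)
phantom <- defaultPhantom(seed = 1)
protos  <- paperProtocols()
orients <- c(0, 30, 60, 90, 120)

mese  <- lapply(orients, function(o) simulateSeries(phantom, protos$MESE_T2, o))
maps  <- lapply(mese, fitMap)
stack <- buildOrientationStack(mese, maps)
transforms(stack)[[4]]
#> RigidTransform2D: rotation -89.801 deg, translation (-0.053, -0.074) vox, center (32.5, 32.5)

aniso <- anisotropyMap(stack)
roi   <- phantomRoiMask(phantom)
stats <- roiStats(stack, aniso, roi, labelNames = attr(roi, "layers"))
print(stats[, c("roi", "nVoxels", "meanAnisotropy", "sdAnisotropy")], digits = 3)
#>            roi nVoxels meanAnisotropy sdAnisotropy
#> 1  superficial     175          0.588       0.0147
#> 2 transitional     175          0.495       0.0156
#> 3       radial     250          0.591       0.0149
#> 4    isotropic      49          0.033       0.0114

analyticAnisotropy(tissueModel(), 0, orients, "MESE_T2")
#> [1] 0.5851393
```

The physical 90° rotation is recovered to 0.2°/0.1 voxel; the measured
radial-zone T2 anisotropy (0.591, i.e. 59.1%) matches the generator's
closed-form value (0.585) to well within the voxel noise, and the isotropic
reference disc shows only the small residual Rician noise bias (0.033).
`runPipeline(pipelineConfig(...))` executes the same chain end to end from
files on disk, writing fitted maps, registered stacks, anisotropy maps and
the per-ROI CSV report.

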