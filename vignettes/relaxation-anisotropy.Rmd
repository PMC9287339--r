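---
title: "Quantifying relaxation anisotropy from multi-orientation qMRI"
author: "RelaxAniso authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying relaxation anisotropy from multi-orientation qMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In tissues with ordered collagen architecture the residual dipolar coupling
between water protons depends on the angle θ between the fiber axis and the
main magnetic field B0. Transverse-family relaxation times (T2, low-amplitude
CW-T1ρ, adiabatic T2ρ, RAFF) therefore change — often severalfold — as a
specimen is physically rotated in the magnet, with the slowest relaxation at
the magic angle (54.7356°, where P2(cos θ) = (3cos²θ − 1)/2 vanishes).
Longitudinal T1 and adiabatic T1ρ are, empirically, orientation-insensitive.

RelaxAniso quantifies this effect from a multi-orientation, multi-sequence
relaxometry experiment: a 2D slice through the specimen, perpendicular to the
rotation axis, imaged with the full protocol set at each of several physical
orientations (nominally 0°, 30°, 60°, 90°, 120°, chosen to bracket the magic
angle). The pipeline output is, per relaxation quantity, a voxel-wise
Michelson anisotropy map

\[ A = \frac{T_{max} - T_{min}}{T_{max} + T_{min}} \]

over the orientation axis, and per-ROI summaries. A is dimensionless in
[0, 1], scale-invariant, and — an exact algebraic identity asserted by test —
the same whether computed on relaxation times or their reciprocal rates.

## Signal models and fitting

All acquisitions are fitted voxel-wise by minimizing the sum of squared
residuals between model and magnitude data:

* **Monoexponential (2 parameters, S0 and T)** for MESE T2 (echo times),
  CW-T1ρ (spin-lock durations) and the adiabatic T1ρ/T2ρ pulse trains, whose
  time axis is the train duration t = n·τp (τp = 4.5 ms). Relaxation during
  the pulses is not modeled separately: the decay is fitted against the train
  length, which is how such data are acquired and tabulated.
* **Magnitude inversion recovery** |S0(1 − 2e^(−TI/T1))| for IR-T1. The
  full-recovery form is used because TR = 7 s far exceeds tissue T1 (~1.5 s);
  the neglected (1 + e^(−TR/T1)) factor would perturb S0 by < 1% and T1 by
  far less. The fit operates on magnitude (not phase-corrected) data because
  the whole pipeline consumes magnitude images; the null-point kink is
  handled transparently by the bounded least-squares solver.
* **RAFF with steady state**: S(t) = S_ss + (S0 − S_ss)e^(−t/T), measured
  with and without an inversion preparation. Both curves are fitted jointly
  with four free parameters (S0, S0inv, S_ss, T), sharing T and S_ss. S0inv
  is left free rather than tied to −S0 or to 2S_ss − S0: the inversion
  efficiency of a real preparation is unknown, and on noiseless synthetic
  data the free parameterization recovers every generating value exactly, so
  nothing is lost. The model magnitude |S(t)| is compared to the data, which
  makes the inverted curve's zero crossing consistent with magnitude images.

**Noise floor.** Magnitude MR images are Rician; at low SNR the background
bias inflates late-time samples and biases T downward. The noise floor is
estimated as the mean background magnitude of the last (lowest-SNR) frame —
from a user mask or, by default, the four 8×8 image corners — and subtracted
in quadrature before fitting: S' = sqrt(max(S² − σ_f², 0)). Quadrature is the
first-order correction implied by E[M²] = S² + 2σ², and the test suite
verifies by Monte-Carlo that it strictly reduces the |bias| of fitted T2 at
SNR 10 relative to no subtraction.

**Numerical choices.** Levenberg–Marquardt with box bounds
(`minpack.lm::nls.lm`, numerical Jacobian): T ∈ [0.1 ms, 20 s], amplitudes in
[0, 10 × max sample] (S0inv in ±10 × max). Initialization: S0 ← max sample;
T ← time-axis span / log(S_first/S_last), clamped to [1 ms, 10 s]; IR-T1
starts from the null-point heuristic TI_min-signal/ln 2; RAFF S_ss starts at
the mean of the two curves' last samples. Cost tolerance 1e−15: noiseless
forward-simulated data refit to the generating parameters at machine
precision for every protocol (the suite asserts 1e−6 relative). A voxel is
*valid* only if the solver converged (an exactly-zero residual also counts)
with T strictly inside the bounds; all-zero or non-finite voxels are invalid,
never errors. The foreground is `first-frame signal > 3·σ_f`; background
voxels are excluded from all downstream maps.

## Registration

Physical rotation of the specimen is predominantly in-plane because the
imaging slice is perpendicular to the rotation axis, so a 2D rigid transform
(rotation + translation about the grid center) is estimated — once per
orientation, from the first MESE echo image against the first orientation —
and applied to every quantity's maps of that orientation, keeping all
quantities mutually consistent. The estimate maximizes normalized
cross-correlation: a coarse rotation grid (−150° … 150°, 5° steps) with the
translation at each candidate resolved by phase correlation, followed by
Nelder-Mead refinement of (θ, dx, dy). Relaxation-time maps are resampled
with bilinear interpolation (validity masks nearest-neighbor; out-of-field
or partially-invalid support ⇒ invalid), i.e. maps are warped, not refitted
from warped raw images — matching the order "fit, then co-register the
maps". The suite verifies recovery of simulated rotations {30, 60, 90, 120}°
within 0.5° and 0.5 voxel at SNR 50, and ≥ 98% layer-label agreement after
alignment.

## Anisotropy and ROI statistics

A is computed on relaxation **times** over orientations, inside the joint
validity mask (the AND of all resampled masks): a voxel invalid at any
orientation is excluded entirely, because a min/max over a voxel-dependent
subset of orientations would bias A inconsistently. Two ROI statistics are
reported:

* `meanAnisotropy` — the mean of voxel-wise A over the ROI (primary, matching
  the anisotropy-map-then-ROI-average convention), with its SD;
* `anisotropyOfMeans` — the Michelson contrast of the ROI-mean times.

The distinction matters for *orientation-independent* quantities. For equal
true values with voxel noise, A is a range statistic with strictly positive
expectation, E[A] ≈ 1.16·σ_T/T for five orientations; it decreases with SNR
but never reaches zero. At SNR 50 the per-voxel precision of a fitted time
constant is a few percent, so voxel-wise mean A sits near 0.03–0.05 even for
a perfectly isotropic signal — this noise floor of the statistic is a
property of the estimator, not a bug, and the isotropic-disc check in the
acceptance suite is bounded accordingly (< 0.05). In `anisotropyOfMeans` the
voxel noise averages out before the min/max is taken, so for an
orientation-independent quantity it falls to a few tenths of a percent; it is
the appropriate check that a quantity is truly orientation-insensitive, and
the suite asserts it < 0.02 for the adiabatic-T1ρ family. For genuinely
anisotropic quantities the two statistics agree closely. The cross-sample
report table aggregates mean A in percent per quantity × ROI.

## The synthetic rotating phantom

The generator produces data with exactly the statistical structure the
analysis assumes, so every stage can be validated against closed forms.

* **Geometry** (64 × 64 voxels): a cartilage-like block of depth zones with
  the canonical fiber arrangement — superficial (fibers 90° to the sample
  axis), transitional (45°), radial (0°) — a signal-free bone band, and an
  isotropic reference disc. The geometry is rotated analytically with the
  physical orientation (labels are evaluated on back-rotated coordinates),
  so the registration stage has real work and no interpolation contaminates
  the ground truth.
* **Relaxation**: R2(θ) = R2_iso + s_q·R2_aniso·P2(cos θ)², the standard
  residual-dipolar form, with θ the effective fiber-to-field angle
  (rotation + fiber offset folded into [0°, 90°]). Defaults: T1 = 1.4 s,
  R2_iso = 10 s⁻¹, R2_aniso = 30 s⁻¹ (cartilage-like at 9.4 T; radial-zone
  T2 ranges 25–95 ms across orientations). Per-quantity scales s_q — T2 and
  Ad-T2ρ 1.0, RAFF2 0.75, RAFF3 0.70, RAFF4 0.50, Ad-T1ρ 0 — emulate the
  observed ordering of transverse-family anisotropies parametrically; no
  rotating-frame physics is simulated. The isotropic disc uses R2 = 20 s⁻¹
  (T2 = 50 ms, mid-range of the MESE echo axis) so the reference fit is
  well-conditioned, and R2_aniso = 0.
* **Spin-lock dispersion**: the anisotropic term of CW-T1ρ is attenuated by
  a single Lorentzian 1/(1 + (2ω1·τ_d)²), ω1 = 2π·f_SL, τ_d = 0.3 ms — the
  simplest form that reproduces the monotone suppression of orientation
  dependence with spin-lock amplitude; at 5 kHz the anisotropic term is
  < 0.5% of its 200 Hz value.
* **RAFF**: S_ss = 0.3·S0, S0inv = −0.95·S0 (95% inversion efficiency).
* **Noise**: Rician, M = sqrt((S + n₁)² + n₂²), n ~ N(0, σ²); default σ = 2
  against a proton density of 100, i.e. SNR 50. Each series' stream derives
  deterministically from the master seed via a 31-bit hash of
  (sample, quantity, orientation, inversion flag), so simulations are
  bit-reproducible and independent across series.
* **Oracle**: `analyticAnisotropy()` evaluates the Michelson contrast of the
  closed-form T(θ_eff) at the sampled orientations — e.g. 0.585 for the
  radial zone with the default five orientations — and is the target the
  end-to-end tests recover within 0.03 at SNR 50 (exactly, to 1e−4, in the
  noiseless chain).

**What the phantom does not emulate** — and hence what passing tests do not
establish about scanner data: B0/B1 inhomogeneity (air bubbles, bone
interfaces), through-plane fiber dispersion and 3D structure, exchange- or
Bloch-level rotating-frame effects (adiabatic/RAFF contrasts are
parametric), partial volume beyond the layer boundaries, and deformable
specimen motion. ROIs are exact interior erosions of the known layers
(margin 2 voxels), whereas real ROIs are drawn by hand.

## Problem sizes and reproducibility

The validation suite runs the full chain at the study conditions — five
orientations, all eleven protocols at their printed timing axes, the 64 × 64
phantom at SNR 50 — with Monte-Carlo checks at 400–1000 replicate voxels;
these sizes give comfortable statistical margins for every asserted bound
while keeping a complete run in tens of seconds on one core. All randomness
flows from a single seed through the per-series hash, so any run is exactly
repeatable; `runPipeline()` is deterministic end to end, and rerunning it
with the same configuration reproduces the report byte for byte.

## Known limitations

* Five orientations under-sample the orientation curve; A is a lower bound
  on the true contrast (adding orientations can only widen min/max, which
  the suite asserts). No (3cos²θ − 1)² model is fitted to measured
  orientation curves to extrapolate beyond the sampled angles.
* Registration is strictly in-plane rigid; out-of-plane specimen motion is
  not recovered.
* The noise-floor estimator assumes signal-free corners (or a user mask);
  specimens touching the image corners require an explicit mask.
* Voxel-wise mean A carries the range-statistic noise bias discussed above;
  compare orientation-independent quantities via `anisotropyOfMeans`.
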