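---
title: "Evaluating microbeam radiotherapy plans with EUD and EQD2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating microbeam radiotherapy plans with EUD and EQD2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtdose)
```

## The problem

Microbeam radiotherapy (MRT) delivers synchrotron-grade kilovoltage X-rays
as lattices of planar beamlets tens of micrometers wide. The dose inside a
single CT voxel is therefore extremely heterogeneous: peak doses of
hundreds of Gy alternate with valley doses an order of magnitude or two
lower over a 400 µm period. Clinical treatment plans, dose constraints and
clinical experience are all expressed on the CT-voxel scale, so comparing
an MRT plan with a conventional plan requires a principled reduction of
the microscopic dose pattern to one number per voxel.

`mrtdose` implements that reduction via the *equivalent uniform dose*
(EUD): the homogeneous dose that produces the same clonogenic cell
survival as the heterogeneous distribution under the linear quadratic
model (LQM). Both the MRT EUD (treated as a single temporal fraction) and
the fractionated clinical dose are then mapped to the common EQD2 scale,
on which DVH metrics and organ-at-risk (OAR) constraints are evaluated.

## Model and procedure

**Survival and EUD.** Each voxel's microscopic dose is summarized by a
histogram of volume fractions $w_i$ at doses $D_i$. Survival is
$SF = \sum_i w_i e^{-\alpha D_i - \beta D_i^2}$ and the EUD is the
positive root of $\beta E^2 + \alpha E + \ln SF = 0$. Because the
histogram bins partition the voxel, $\min D_i \le EUD \le \max D_i$
always; a uniform voxel returns its own dose, and a voxel bathed in
homogeneous scatter returns the plain sum of the scatter doses.

**Histogram reduction.** Subvoxel doses are sampled on an isotropic 25 µm
lattice (samples at subvoxel centers), sorted ascending, and split into 35
contiguous groups of as-equal-as-possible size; $D_i$ is the group mean
and $w_i$ the group's share of the samples. We read "equal groups" as
equal *count*, not equal dose width — sorting first only matters for a
quantile partition. When the sample count is not divisible by 35 the
remainder goes one extra sample per group starting from the lowest-dose
group, and the weights carry the true group sizes, which makes weight and
mean conservation exact (the $\le 1$ ulp floating-point residual of
`sizes/n` is absorbed into the last weight). With fewer samples than
groups the reduction degenerates to one singleton bin per sample.

**Fractionation.** $EQD2 = D\,(d + \alpha/\beta)/(2\,\mathrm{Gy} +
\alpha/\beta)$. For clinical maps $d$ is the per-fraction dose (fixed, or
voxel dose / number of fractions); for MRT maps the delivery is one
temporal fraction, so each voxel's whole EUD is its fraction dose. We take
$d = EUD$ per voxel because no other per-fraction dose is defined for a
single-fraction heterogeneous delivery; this is the natural reading and
makes the conversion exact for the uniform case.

**Tissue parameters.** A CSV registry maps structure labels to $\alpha$
(Gy⁻¹) and $\beta$ (Gy⁻²); the ratio is derived rather than stored because
published ratios are often rounded. Voxels covered by several contours
take the highest-priority label's parameters — targets before OARs by
default, since an OAR overlapping the PTV is, inside the overlap, being
treated as target. Uncontoured tissue falls back to $\alpha = 0.1$,
$\beta = 0.05$. The overlap rule is a documented assumption: clinical
practice delineates overlaps case by case.

## The dose engine and its assumptions

The engine is a transparent analytic lattice model, deliberately simple so
that every downstream quantity has a closed-form check; any other producer
of subvoxel dose blocks can be plugged into the histogram/EUD chain.

* **Lateral profile**: periodic, 1 inside 50 µm peaks, a constant
  `valley_fraction` elsewhere (default 0.05 — transport engines do not
  publish this number; it is a free parameter here, chosen to give
  single-field PVDRs of ~20, in the range reported for clinical-size
  fields). An optional Gaussian penumbra (`pnorm` edge smearing including
  neighbouring peaks) makes the profile continuous.
* **Depth dose**: exponential in radiological depth with one effective
  attenuation coefficient (default 0.17 cm⁻¹ ≈ water at ~104 keV mean
  photon energy), replacing a full spectrum. Radiological depth is
  integrated by voxel ray traversal once per (voxel, beam) to the voxel
  center, then corrected to first order with the local density for each
  sample's along-beam offset — exact for locally homogeneous voxels.
* **Cross-firing**: coplanar gantry angles about z; fields superpose by
  plain summation. Conformal apertures are the target silhouette projected
  into the beam's-eye plane (voxel centers rasterized at half the voxel
  pitch) dilated by 1–2 pixels; the dilation absorbs the voxel-footprint
  edge effects of center-based rasterization.
* **Lattice phase** is anchored at the isocenter (a peak plane passes
  through it); the choice is configurable and unstated in the field.
* **Out-of-field dose** is zero by default; an optional uniform scatter
  fraction exercises the homogeneous-scatter limit of the EUD.

Known simplifications: no Monte Carlo scatter (so the single-field PVDR is
depth-independent here, which real scatter physics violates), no
polyenergetic spectrum, no beam divergence, no lung microstructure, no
organ motion, no interlacing. Passing tests therefore validate the
reduction and evaluation chain, not transport physics.

Within a voxel the analytic dose field is constant along z (coplanar
beams, microbeam planes containing z), so per-voxel histograms are built
from the in-plane 25 µm sample sheet; replicating the sheet across z
leaves an equal-count histogram unchanged. We read the "25 µm" subvoxel
resolution as an isotropic 25 µm pitch. With the default 2 mm voxels this
is an 80×80 sheet (6400 samples) per voxel per beam.

## Numerical choices

* $\ln SF$ is accumulated in log space (log-sum-exp), so peak doses of
  hundreds of Gy underflow to their correct negligible contribution rather
  than poisoning the sum; `survival_fraction` returning an exact 0 raises
  a classed warning, while the EUD path never exponentiates. Extremely
  high peak doses are thus handled gracefully — their precise survival is
  irrelevant to the voxel total.
* $\beta = 0$ uses the linear limit $EUD = -\ln SF / \alpha$ explicitly.
* $D_{x\%}$ uses the hottest-volume step convention: the dose of the voxel
  in which the cumulative (hottest-first) volume reaches $x\%$ — on 100
  equal voxels of 1..100 Gy, D98% = 3 Gy and D2% = 99 Gy. Absolute-volume
  metrics ($D_{0.1\,cm^3}$, $D_{150\,cm^3}$) default to linear
  partial-voxel interpolation because they are sensitive to voxel
  granularity; both conventions are exposed and tested.
* D98% normalization is solved on the final EQD2(EUD) map — the quantity
  plans are compared on — with `stats::uniroot` on the single beam-weight
  factor. The engine is linear in that factor, so candidate maps only
  rescale cached histograms; the solve is exact to ~1e-7 and idempotent.
* Ties across histogram group boundaries stay in place (stable positional
  split): deterministic, and immaterial because tied values are equal.

## Binning fidelity

The 35-bin reduction is exact for uniform voxels and conserves the mean
exactly. For bimodal peak/valley mixtures at in-field dose levels (valley
8–30 Gy, PVDR up to 100) the binned EUD stays within 1% of the EUD
computed on all samples — verified against a brute-force un-binned oracle.
The error is concentrated in the single group that straddles the two
modes: its weight is at most 1/35, bounding the $\ln SF$ shift by roughly
0.04, which is negligible against $(\alpha + 2\beta E)E$ at clinical
in-field EUDs but can reach several percent when the valley EUD is ~1–3
Gy. Out-of-field dose estimates at very low levels should therefore use
more bins or the raw samples (both supported).

## The synthetic phantom

`generate_phantom()` rasterizes a declarative spec: a water cylinder (or
slab) in air, an ellipsoidal target, spherical OARs — one overlapping the
target in the default head-like spec, exercising parameter priority — and
an optional 0.26 g/cm³ lung-like compartment. Generation is deterministic;
the seed only feeds an optional density-noise term. The phantom emulates
the *geometry* of clinical scenarios (shallow/deep targets, OAR-target
overlap, low-density regions), not CT heterogeneity, anatomy, or
Hounsfield calibration — which is exactly what the engine-agnostic
evaluation chain needs.

Test and example problem sizes are chosen for tight feedback loops: a
16×16×3 grid at 3 mm for engine property tests, the 32×32×8 default
phantom at 2 mm (208 PTV voxels, ~6400 subvoxel samples each per beam) for
end-to-end runs. The chain is O(simulated voxels), and `simulate_plan()`
takes a voxel-selection mask so that studies pay only for the structures
they evaluate.

## Limitations

Beyond the engine simplifications above: the LQM itself is contested for
fraction doses far above $\alpha/\beta$ (literature supports validity up
to ~18 Gy per fraction; MRT valley/EUD levels mostly comply, peak doses do
not need to); repair kinetics, immune and bystander effects are outside
the model; no dose optimization is provided — plans are shaped by target
projection only, which tends to over-dose OARs directly behind the target
relative to optimized clinical plans; dose-to-medium vs dose-to-water
conversion is not applied.
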