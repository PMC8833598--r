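# mrtdose

Dose simulation and treatment-plan evaluation for **microbeam radiotherapy
(MRT)** — spatially fractionated kilovoltage X-ray therapy delivered as
lattices of ~50 µm planar beamlets spaced a few hundred µm apart. MRT dose
distributions vary by an order of magnitude over tens of micrometers
(peak/valley structure), so they cannot be compared with conventional,
CT-voxel-scale clinical dose distributions directly. `mrtdose` implements
the comparison chain used in MRT treatment-planning research:

1. **Microscopic dose engine** — an analytic model of cross-firing conformal
   microbeam fields on a voxelized density grid: periodic peak/valley
   lateral profiles (peak width 50 µm, center-to-center 400 µm by default),
   exponential depth attenuation with an effective coefficient for ~104 keV
   photons, conformal apertures built by projecting the target volume along
   each coplanar beam and dilating it by 1–2 voxels.
2. **Subvoxel reduction** — within each CT-scale voxel the dose is sampled
   on a 25 µm lattice, sorted, and arranged into 35 equal-count groups,
   giving a per-voxel dose histogram (wᵢ, Dᵢ).
3. **Equivalent uniform dose (EUD)** — the homogeneous dose with the same
   clonogenic survival under the linear quadratic model,

       SF  = Σᵢ wᵢ · exp(−α·Dᵢ − β·Dᵢ²)
       EUD = −α/(2β) + √((α/(2β))² − ln(SF)/β)

   with tissue-specific α (Gy⁻¹) and β (Gy⁻²) resolved per voxel from the
   structure contours (default normal tissue: α = 0.1 Gy⁻¹, β = 0.05 Gy⁻²).
4. **EQD2 conversion** — every dose is expressed as the equivalent total
   dose in 2 Gy fractions, EQD2 = D·(d + α/β)/(2 Gy + α/β); MRT is treated
   as a single temporal fraction (d = EUD per voxel).
5. **Plan evaluation** — DVHs, D98%/Dmean/D2%/Dmax/V\_Gy/D\_cc metrics under
   the hottest-volume convention, normalization of the MRT plan so its PTV
   D98% matches the clinical reference, and pass/fail reports against
   organ-at-risk EQD2 constraint tables.

The package is aimed at medical-physics researchers exploring which
clinical scenarios suit MRT; it ships a deterministic synthetic phantom
generator (body cylinder + target + overlapping OARs) so that every stage
runs and is tested without patient data.

## Worked example

```r
library(mrtdose)

ph <- generate_phantom(default_phantom_spec(), seed = 1)
ph$structures
#> <structure_set> 3 structures on 32x32x8 grid: ptv_gbm_cavity (208 vox),
#>   brain_stem (56 vox), cochlea (8 vox)

beams <- arrange_beams(c(0, 120, 240), ph$structures$masks$ptv_gbm_cavity,
                       ph$structures$spacing, ph$structures$origin,
                       entrance_peak_dose = 100)

# microscopic dose in one PTV voxel -> 35-bin histogram -> EUD
blk <- sample_subvoxel_doses(c(20, 13, 4), beams, ph$density, collapse_z = TRUE)
h <- build_histogram(blk)
h
#> <dose_histogram> 35 bins, dose range [9.174, 140.1] Gy, mean 30.99 Gy
reg <- read_tissue_table()
eud_from_histogram(h, reg$ptv_gbm_cavity)
#> [1] 10.34892
```

The voxel's mean physical dose is 31 Gy, but its survival-equivalent
uniform dose is only 10.3 Gy: most of the volume sits in valleys, and the
extreme peak doses barely change the total survival.

```r
region <- Reduce(`|`, ph$structures$masks)
sim <- simulate_plan(ph$density, beams, voxels = region)
ans <- normalize_to_reference_d98(sim, 53.05, ph$structures$masks$ptv_gbm_cavity,
                                  ph$structures, reg)
ans$factor
#> [1] 1.447069
q <- eqd2_map(eud_map(ans$sim, ph$structures, reg), ph$structures, reg)
round(c(D98 = dose_metric(q, ph$structures$masks$ptv_gbm_cavity, "Dpct", 98),
        Dmean = dose_metric(q, ph$structures$masks$ptv_gbm_cavity, "Dmean"),
        D2 = dose_metric(q, ph$structures$masks$ptv_gbm_cavity, "Dpct", 2)), 2)
#>   D98 Dmean    D2
#> 53.05 56.12 59.11

cons <- list(constraint_spec("brain_stem", "Dmax", 54),
             constraint_spec("cochlea", "Dmax", 45))
evaluate_constraints(q, ph$structures, cons)
#>    structure metric arg threshold achieved units  pass
#> 1 brain_stem   Dmax  NA        54 55.16968    Gy FALSE
#> 2    cochlea   Dmax  NA        45 25.50448    Gy  TRUE
```

After scaling the beam weights by 1.447, the PTV D98% of the EQD2(EUD) map
matches the 53.05 Gy reference exactly; the brain-stem OAR — which
overlaps the PTV in this phantom and therefore sits inside the conformal
fields — exceeds its 54 Gy maximum-dose limit, while the cochlea passes.

A whole scenario can also be declared in one YAML config (phantom, beams,
tissue table, reference D98%, constraints) and run in a single call:

```r
res <- run_plan(system.file("extdata", "example_plan.yaml", package = "mrtdose"))
res$report
```

A thin command-line front end over the same functions is installed at
`system.file("cli", "mrtdose.R", package = "mrtdose")` with subcommands
`eqd2`, `phantom`, `simulate` and `evaluate`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mrtdose.R",package="mrtdose"))')" \
  eqd2 --dose 37.5 --per-fraction 12.5 --alpha-beta 10
# 70.31
```

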