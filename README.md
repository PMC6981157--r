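# mechanoct

Quantifying the mechanical regulation of bone defect healing from
time-lapsed micro-CT density images.

## What it does, and for whom

During the healing of a stabilised femoral defect, new mineralised tissue
preferentially appears where the local tissue-scale mechanical stimulus is
high, and existing bone surfaces form, rest or resorb depending on the
strain they carry. `mechanoct` is an R implementation of the full
computational chain used to test that hypothesis on weekly in vivo
micro-CT series, intended for researchers in bone mechanobiology and
skeletal imaging:

1. **Image processing** — Gaussian pre-filter (σ 1.2, support 1 voxel),
   multi-density threshold ladder (395–720 mg HA/cm³ in 25 mg HA/cm³
   steps), translation registration, and overlays of consecutive binarised
   frames into formation / quiescence / resorption / background labels.
2. **Volumes of interest** — automatic partition of the post-operative
   image into defect centre (DC), defect periphery (DP), cortical
   fragments + marrow (FC) and fragment periphery (FP) via component
   labelling at 645 mg HA/cm³, marrow flood-fill, signed-distance
   interpolation of the periosteum across the gap, and ray casting.
3. **Micro-FE** — each voxel becomes a trilinear hexahedral element;
   density maps to Young's modulus linearly between 4 GPa (395) and
   14 GPa (720), background gets 3 MPa, ν = 0.3 everywhere; a matrix-free
   Jacobi-preconditioned conjugate-gradient solver produces the
   strain-energy density U and the effective strain
   `ε_eff = sqrt(2U/E)` at element centroids.
4. **Load translation** — physiological loads estimated on an intact shaft
   by homogenising the strain-energy density over unit load cases, then
   transferred to image-edge displacement boundary conditions through a
   two-spring fixator/callus model: `u = F / (k_fix + k_callus)`, with
   the callus stiffness probed by 1 % axial compression.
5. **Mechanoregulation statistics** —
   ROC analysis of the strain preceding mineralisation (candidates =
   non-bone voxels in DC ∪ DP; AUC; optimal point = argmax of
   Youden's J = TPR − FPR), and the two-threshold mechanostat classifier
   on the bone surface (resorption below `T_R`, formation above `T_F`,
   quiescence between) scored by a category-normalised confusion matrix
   whose mean diagonal is the correct classification rate,
   `CCR = (C_FF + C_QQ + C_RR)/3`, swept over a (T_R, T_F) grid into heat
   maps.
6. **Kinetics** — BV/TV time courses and formation/resorption rates per
   VOI and density threshold.
7. **Synthetic phantom** — a gapped elliptical-tube defect evolved by a
   *known* mechanostat rule (formation where `ε_eff > T*`, resorption
   below `T_R*`, Bernoulli flip noise, density maturation), with an event
   log recording every true event and the preceding strain field, so that
   the entire pipeline is testable by parameter recovery without any
   external data.

## Worked example

A desk-scale healing study: the default 0.85 mm defect in a
0.8 × 0.4 mm elliptical tube, discretised at 30 µm, healed for three
weekly steps under a 10 N axial load shared with a 25 N/mm fixator.

```r
library(mechanoct)

geom <- phantom_geometry(grid_shape = c(32, 32, 56), voxel_size = 30,
                         outer_major_axis = 0.8, outer_minor_axis = 0.4,
                         cortical_thickness = 0.1, gap_length = 0.85)
phantom <- build_phantom(geom)
phantom
#> <density_image> 32 x 32 x 56 voxels @ 30 um, frame 0
#>   density range [0.0, 900.0] mg HA/cm^3

rule <- healing_rule(flip_noise = 0.02, rng_seed = 101)  # T* = 0.30
sim  <- simulate_healing(phantom, rule, phantom_loading(), n_steps = 3, geom)

vois <- define_vois(sim$series[[1]])
vois
#> <voi_set> DC 13888 | DP 17808 | FC 7840 | FP 17808 voxels
#>   TV_defect 0.375 mm^3, TV_fragment 0.2117 mm^3

# week-2 analysis: overlay frames 1 -> 2, strain preceding step 2
ov  <- overlay(binarize(sim$series[[2]], 395), binarize(sim$series[[3]], 395))
roc <- roc_analysis(sim$events$steps[[2]]$eff_strain, ov, vois$DC | vois$DP)
roc
#> <roc_result> AUC 0.9756, T_opt 0.3001 (TPR 0.991, FPR 0.042), 16505+/7555-

sm <- extract_surface_states(ov, sim$events$steps[[2]]$eff_strain)
ccr_heatmap(sm)
#> <remodel_heatmap> 64 thresholds, max CCR 0.8174 at (T_R 0.0002515, T_F 0.00182)

sapply(sim$events$steps, `[[`, "closure")   # mm
#> 0.386 0.372 0.322
sapply(sim$events$steps, `[[`, "k_callus")  # N/mm
#> 1.88 6.07 1459.39
```

Reading the numbers: the ROC recovers the generator's formation threshold
(`T_opt` 0.3001 against the true `T*` = 0.30) with AUC 0.98 — mineralising
soft-tissue voxels were indeed the high-strain ones, up to the 2 % flip
noise. The surface heat map puts the optimal resorption threshold at
2.5e-4, next to the generator's disuse setpoint `T_R*` = 2e-4 (surface
signals live on the bone strain scale, 1e-4…1e-3, far below soft-tissue
strains). The closing displacement falls while the probed callus stiffness
rises — and jumps three orders of magnitude once the defect bridges —
which is stress shielding emerging from the two-spring load-sharing model.

The same study runs end to end, with CSV tables, MetaImage volumes, a JSON
manifest and a Markdown report, via:

```r
cfg <- study_config(geometry = geom, rule = rule, n_steps = 3, seed = 1)
res <- run_study(cfg, "scratch/demo_study")
make_report("scratch/demo_study")
```

or from the shell through the CLI (`inst/cli/mechanoct`): subcommands
`phantom`, `segment`, `voi`, `solve`, `estimate-load`, `mechreg`,
`kinetics`, `run`, `report`.

## More

The methods vignette
(`vignettes/mechanoregulation-pipeline.Rmd`) documents the model
assumptions, every tunable constant with units and rationale, what the
synthetic phantom does and does not emulate, numerical tie-breaks, and
known limitations.
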