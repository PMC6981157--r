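---
title: "Quantifying mechanoregulation of bone defect healing from time-lapsed micro-CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mechanoregulation of bone defect healing from time-lapsed micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the pipeline answers

During bone defect healing, new mineralised tissue appears where the local
mechanical stimulus is high, and bone surfaces remodel (form, rest, or
resorb) according to the strain they experience. `mechanoct` implements the
computational side of testing that hypothesis with time-lapsed in vivo
micro-CT: weekly density images of a stabilised femoral defect are
segmented, overlaid to detect formation and resorption events, converted
into voxel finite-element models whose effective strain field *precedes*
each event, and finally the association between stimulus and event is
quantified with ROC analysis (for mineralisation in soft tissue) and a
two-threshold mechanostat classifier (for surface remodelling).

Because the in vivo scans behind the original study are not publicly
deposited, the package ships a synthetic phantom generator with a *known*
mechanoregulation rule. Every downstream stage can therefore be validated
in closed loop: the generator writes down which voxels truly formed or
resorbed and which strain field preceded each event, and the analysis must
recover the rule's parameters from the images alone.

## Image processing model

Density images are 3D scalar fields of hydroxyapatite-equivalent mineral
density (mg HA/cm^3) on an isotropic grid (10.5 µm nominal in vivo).
Processing follows the conventional chain:

* **Gaussian pre-filter**, sigma 1.2 voxels, truncation (support) radius 1
  voxel, i.e. a normalised 3×3×3 kernel. Boundaries use symmetric
  (reflective) padding; the choice only matters within one voxel of the
  image face and is documented here because the protocol is silent on it.
* **Multi-density threshold ladder**: binarisation at every threshold from
  395 to 720 mg HA/cm^3 in 25 mg HA/cm^3 steps (14 levels). There is no
  consensus single threshold for healing tissue; carrying the whole ladder
  makes threshold sensitivity part of every result. Comparison is
  *inclusive* (`density >= tau`), so a voxel exactly at a threshold belongs
  to that mask.
* **Overlay** of consecutive binarised frames at the same threshold:
  formation = bone only at t+1, resorption = bone only at t, quiescence =
  bone at both, background = neither. The conservation identities
  |F| + |Q| = BV(t+1) and |R| + |Q| = BV(t) hold exactly and are asserted
  in the tests.
* **Registration** is translation-only (integer voxel offsets by maximum
  normalised cross-correlation, FFT accelerated). The full rigid
  registration of the reference protocol is out of scope; synthetic series
  are generated pre-registered, so registration here is a robustness
  feature for externally supplied series, not a correctness dependency.

## Volumes of interest

Four disjoint VOIs partition the image, derived automatically from the
post-operative frame. The frame is used *unfiltered* here: the 645
mg HA/cm^3 debris threshold sits roughly ten noise standard deviations
above soft tissue, so filtering buys nothing, whereas smoothing a sharp
osteotomy edge drags the terminal cortical slices to about 0.707 × the
cortical density — directly onto the threshold knife edge, where image
noise would toggle whole end slices in and out of the mask. The image is
binarised at 645 mg HA/cm^3 (chosen to
disconnect surgical debris), connected components are labelled
(26-connectivity by default) and the two components touching the opposite
axial faces become the cortical fragments. Per-slice flood filling closes
the marrow cavities, giving FC. The last intact cross-sections on either
side of the gap are interpolated across it by linear blending of their 2D
signed distance maps (thresholded at zero), reconstructing a virtual
periosteum; distance-map blending is the standard shape-interpolation
device and avoids staircase artefacts of voxel-wise blends. Rays cast from
the four transverse image boundaries along the in-plane axes assign the
voxels between the boundary and the first struck surface to the fragment
periphery FP (strike on FC) or defect periphery DP (strike on the virtual
surface); where both claims meet, FP wins. The defect centre DC is the
complement, so the partition is exhaustive by construction. "Struck"
is read as *first* intersection: peripheries lie outside the periosteum,
and letting a ray keep painting past the impact point would place bone
interior voxels into their own periphery, contradicting disjointness.

Reference volumes for normalisation are TV_defect = |DC| and TV_fragment =
|FC| (in mm^3): the intact-bone volume healing aims to restore.

## Micro-FE model

Each voxel becomes one 8-node trilinear hexahedral element (geometrically
identical, so a single reference stiffness matrix scaled by the element
modulus assembles the system implicitly). Material behaviour is linear
elastic with a uniform Poisson's ratio of 0.3:

* density < 395 mg HA/cm^3 → 3 MPa (soft tissue / background),
* density in band [tau_k, tau_{k+1}) → E = 4000 + 10000·(tau_k − 395)/325
  MPa, i.e. 4 GPa at the 395 anchor and 14 GPa at the 720 anchor,
  clamping above 720. The per-band ("thresholded images") mapping is the
  default; a continuous linear mode exists for sensitivity checks.

The system is solved matrix-free with Jacobi-preconditioned conjugate
gradients to a relative residual of 1e−8 (default; the phantom loop uses
1e−6, far below the 1e−2 resolution at which strains are
threshold-compared). The solver is deliberately small-scale: the same
mathematical object as the production HPC solvers for 10^8-DOF models, but
auditable against a dense direct factorisation, which the test suite does
on every grid up to 5^3 with random two-material fields.

Strains are evaluated at the element centroid, which for trilinear
hexahedra equals the mean over the 2×2×2 Gauss points. The stimulus is the
effective strain `eps_eff = sqrt(2U/E)` (U = strain-energy density):
under displacement control it is invariant to uniform modulus scaling,
which is the reason it is preferred over SED as a threshold variable.

The defect's axial stiffness is probed by prescribing a 1% axial
compression across the cortical bone + marrow column with free transverse
faces; `k = reaction / displacement`. Elements outside the probed region
are softened by a factor 1e−3 relative to the weakest region material
rather than removed — this keeps the operator definite while contributing
a negligible parallel path, and keeps the probe exactly linear in a global
modulus scaling.

## Load translation: the two-spring model

Physiological loading is estimated on an intact shaft by finding
non-negative combinations of unit load cases (axial compression 1 N,
optional bending 1 Nmm about the section's minor ellipticity axis) whose
superposed strain field makes the strain-energy density as homogeneous as
possible at a target level U_target (default 0.02 MPa — the homogeneous
tissue-loading level conventionally used by load-estimation methods; the
reference study does not print its value). The SED of a combination is
computed from the superposed strain tensor, never by adding SEDs.

The organ-to-image translation replaces the ~250k-element bone–fixator
model with a lumped two-spring model, justified because the original
coupling uses *only* the axial stiffness of the callus: the axial load F
splits between fixator (k_fix) and callus (k_callus, from the stiffness
probe), giving an interface closing displacement

    u = F / (k_fix + k_callus)

applied as equal-and-opposite displacements of the two axial image faces.
Bending transfer is off by default (its stiffness is uncontrolled in the
reference models as well); an optional linear axial-displacement gradient
across the face is available. As bone bridges the defect, k_callus grows
and u falls — stress shielding emerges from the model rather than being
scripted, and the tests assert its monotonicity across a healing series.

## Statistical engines

**ROC for mineralisation.** Candidates are the voxels that are *not* bone
at time t inside DC ∪ DP; condition positive means mineralised at t+1.
(Voxels that resorb between the frames were bone at t and are therefore
not candidates.) The preceding effective strain is swept as a classifier
threshold (`signal > T` predicts mineralisation); AUC is computed by the
trapezoid rule over the tie-collapsed curve, which the tests pin to the
Mann–Whitney pair-counting statistic to 1e−12. The optimal operating point
is the point furthest from the 45° random line — implemented as the argmax
of Youden's J = TPR − FPR, the same point up to the constant 1/sqrt(2) —
with ties resolved towards the lowest threshold.

**Mechanostat surface classifier.** The bone surface at t is extracted
with a von Neumann (6-connected) radius-1 neighbourhood. Ground truth:
formation = quiescent-bone voxel touching newly formed bone; resorption =
resorbed voxel touching background; quiescence = quiescent-bone voxel
touching background with no formation neighbour. Formation takes
precedence when a voxel satisfies several definitions (the source protocol
does not disambiguate; precedence follows the interface that represents
activity). The signal is sampled at the surface voxel itself; a documented
switch samples the mean over soft-tissue face neighbours instead. The
classifier has two thresholds, resorption below T_R, formation above T_F,
quiescence in the *closed* interval between (boundary values are
quiescent; the printed classifier leaves them unassigned). The confusion
matrix is column-normalised per true category so each event type carries
equal weight regardless of abundance — the printed equation carries no
row index, and the column reading is the one consistent with "diagonal
entries are analogous with true positive rate". CCR = trace/3; empty truth
categories contribute zero and are flagged. The CCR heat map sweeps a
64×64 quantile-spaced grid (resolution unstated in the source; quantile
spacing makes the grid invariant to monotone signal transforms) over the
lower-triangle domain T_R < T_F, ties resolved to the lexicographically
smallest pair.

## The synthetic phantom: a stated world

The phantom emulates exactly the statistical structure the analysis
assumes, nothing more:

| parameter | default | why |
|---|---|---|
| grid / voxel | 96×96×160 at 10.5 µm | desk-scale analogue of the scan geometry |
| tube (full axes) | 0.8 × 0.4 mm, wall 0.1 mm | murine mid-shaft proportions (2:1 elliptical tube, thin wall) scaled to fit the default grid; the anatomical 2.0 × 1.0 × 0.2 mm values do not fit a 1 mm cross-section and remain available on larger grids |
| gap | 0.85 mm (alt. 1.45) | the two defect models |
| cortical density | 900 mg HA/cm^3 | above the whole ladder |
| seed density | 450 mg HA/cm^3 | freshly mineralised tissue enters near the bottom of the ladder; no published value exists, this is stipulated |
| maturation | +100 mg HA/cm^3 per step to 900 | produces the observed lag of high-threshold BV/TV behind low-threshold BV/TV |
| T* (formation) | 0.30 eff. strain | the recoverable ground-truth parameter |
| T_R* (resorption) | 2e−4 | bone-scale disuse setpoint (~200 µstrain); bone strains are 1e−4…1e−3 while defect soft tissue strains are 0.1…0.5, so a resorption threshold of order T* would strip every surface |
| flip noise | 0 (0.02 in acceptance runs) | voxels disobeying the rule |
| conduction radius | auto: ceil(gap_vox/4) | new bone forms only near existing bone; the radius is matched to the observed healing speed — small defects bridge at the lowest threshold by about the second weekly scan. A fixed small radius (e.g. 2 voxels) would stretch bridging over 7+ steps and leave a permanently unmineralisable high-strain core in the gap, degrading week-2 parameter recovery for purely structural reasons |
| loading | F = 10 N, k_fix = 25 N/mm | 10 N is the published physiological estimate; with the probed post-operative callus stiffness (~1 N/mm) the pair puts the nominal gap strain near 0.45, the regime of the reported week-2 optimal effective strain (~0.5). The fixator stiffness is a stand-in for an unpublished calibration |

At each step the rule is applied against the *current* FE solution: soft
voxels within the conduction zone mineralise to the seed density iff
eps_eff > T*, XOR an independent Bernoulli(p) flip; bone surface voxels
with eps_eff < T_R* resorb with the same flip mechanism; surviving bone
matures. The event log records every formed/resorbed/matured voxel and the
preceding strain field — it exists precisely to serve as ground truth for
parameter recovery.

What the phantom does **not** emulate: cartilage and soft-tissue
phenotypes, partial-volume and beam-hardening artefacts, scanner drift and
rotational misalignment, biological heterogeneity between animals, or any
claim of geometric realism beyond a gapped elliptical tube. A green
parameter-recovery test therefore establishes that the *pipeline* is
faithful (segmentation, FE, and statistics recover a known rule through
the imaging chain), not that the rule is biologically complete.

## Numerical choices and tie-breaks

* CG tolerance 1e−8 (solver default), 1e−6 inside the phantom loop;
  iteration cap scales with grid size; non-convergence is an error
  carrying the residual history, never a silent result.
* Threshold comparisons are inclusive (`>=`) so masks at exactly-threshold
  densities are non-empty.
* ROC optimal point: ties → lowest threshold. Heat-map argmax: ties →
  lexicographically smallest (T_R, T_F). Classifier boundary values →
  quiescence.
* Periosteum interpolation parametrises the gap so its first/last slices
  reproduce the adjacent intact outlines exactly; a single-slice gap uses
  the midpoint blend.
* The patch-test effective strain at 1% confined uniaxial compression and
  Poisson 0.3 is sqrt(2·(0.5·0.576923 + 0.384615)·1e−4) = 0.0116024.
* `run_study` with `n_steps = 0` analyses a single post-operative frame:
  VOIs and manifest are produced, kinetics and overlay tables are empty
  (no consecutive pair exists).

## Scale

The production-scale models behind the original analysis have ~25 million
elements and run on HPC clusters; everything here is sized for one CPU.
The acceptance suite runs the same physical phantom (0.85 mm gap,
0.8 × 0.4 mm tube) discretised at 32×32×56 / 30 µm rather than
96×96×160 / 10.5 µm, keeping the full suite within minutes. All geometry
scales through `phantom_geometry()`, and nothing in the implementation is
specific to the reduced size.

## Known limitations

* Translation-only registration; separate proximal/distal fragment
  registration is not implemented.
* The two-spring load translation ignores bending transfer by default and
  its fixator stiffness is a configuration placeholder.
* The stiffness-probe softening floor (1e−3 of the weakest region
  material) adds a sub-0.1% parallel path rather than a true void model.
* On noise-free synthetic data the Gaussian pre-filter slightly erodes
  single-voxel structures, which misaligns overlay labels with the
  generator's raw-image strain field; parameter recovery is therefore
  quoted against the event log's recorded stimulus, with the
  filtered-pipeline variant exercised in the pipeline tests.
* HDF5 persistence is replaced by MetaImage (.mha) volumes plus CSV/JSON
  tables, matching what the runtime environment provides.
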