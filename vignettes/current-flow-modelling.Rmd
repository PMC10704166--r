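---
title: "Current-flow modelling with idealized and as-placed tDCS electrodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Current-flow modelling with idealized and as-placed tDCS electrodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Person-specific models of transcranial direct current stimulation (tDCS)
estimate how much current a montage delivers to the brain by solving the
quasi-static volume-conduction problem on a segmented head. Modelling
pipelines usually *synthesize* the electrodes at their nominal 10–20
positions ("artificial" electrodes). When stimulation is delivered in
practice, pads slip, paste smears, and the as-placed ("real") geometry can
differ enough to change the predicted dose. `tdcsflow` reproduces this
comparison end to end on synthetic head phantoms: it builds a cohort of
heads with graded brain atrophy, places both electrode models on identical
tissue volumes, solves both forward problems, and quantifies how dose
differences track electrode-geometry differences and atrophy.

Because the phantoms are synthetic, the package recovers *mechanisms* —
signs, orderings, significance — rather than any specific cohort's
numbers. The one published quantity that is exactly reproducible, the
percent-difference arithmetic on a published table of per-participant
medians, ships as a plain-text fixture and is reproduced to the printed
precision.

## Forward model

The electric potential obeys the heterogeneous Laplace equation
$\nabla \cdot (\sigma \nabla \varphi) = 0$ with pure Neumann boundary
conditions: a total current $I$ (default 2 mA) enters through the anode pad,
leaves through the cathode pad, and no current crosses the head surface
anywhere else. Current density is $\mathbf{J} = \sigma \mathbf{E} =
-\sigma \nabla \varphi$.

Default conductivities (S/m): white matter 0.126, gray matter 0.276, CSF
1.65, bone 0.01, skin 0.465, conductive paste 0.3178. The rubber pad has no
standard literature value; the default 0.59 S/m is a typical conductive-
rubber figure and is configurable. Air is non-conductive and excluded from
the computational domain.

The discretization is a finite-volume 7-point stencil on the voxel grid.
The face between neighboring voxels $i,j$ carries conductance
$g_{ij} = H(\sigma_i, \sigma_j)\, A/d$ with $H$ the harmonic mean — exact
for flux normal to a layered medium, which is the dominant configuration in
a shelled head. Faces adjacent to air carry zero conductance, which *is*
the zero-flux Neumann condition; no penalty terms or tiny conductivities
are involved, which keeps the operator well-conditioned. The operator is
symmetric with exact zero row sums, so discrete current is conserved to
solver precision; voxels with no conductive neighbor are excluded from the
unknowns (they cannot carry current and would otherwise make the operator
singular).

The singular Neumann system is solved by Jacobi-preconditioned conjugate
gradients (compiled code) with the right-hand side projected onto mean
zero and the gauge fixed by subtracting the mean potential. The default
relative-residual tolerance of 1e-10 is far below discretization error;
a dense direct solve is the test oracle on small grids (agreement to 1e-8
relative). The solver assumes one connected conductive domain; terminal
connectivity is verified by a breadth-first reachability check before each
solve.

A homogeneous cuboid with the pad's 35 cm² cross-section and full-face
terminals is the dose oracle: at 2 mA it must carry
$|\mathbf{J}| = I/A = 0.571$ A/m² (equivalently 0.0571 mA/cm²) uniformly,
and the solver reproduces this to well under 1%. Interior cut-plane fluxes
recover the full 2 mA and the discrete surface leakage is zero to solver
precision.

## Phantoms and atrophy

Phantoms are concentric (optionally ellipsoidal) shells: white-matter core,
4 mm gray-matter shell, CSF, skull, scalp, with default outer radii
58/64/70/77 mm — an approximate adult head; no public segmentation
underlies them. Atrophy is a scale factor in (0, 1] on the brain outer
radius with skull and scalp fixed, so CSF fills the widening gap; an
interior CSF sphere (default 12 mm, scaled by the inverse atrophy factor)
mimics ventricular enlargement. Brain volume ratio, (GM+WM)/(GM+WM+CSF) by
voxel count, is the atrophy proxy: it decreases monotonically in the
atrophy scale, and voxelized compartment volumes agree with the closed-form
shell volumes to a few percent at 2 mm, converging under refinement.

The default cohort spreads 16 atrophy scales evenly over [0.86, 1.0] with
seeded jitter on the spacing, shell radii (1.5% SD) and axis scales (2%
SD). The atrophy range is a package choice, not a published value: the
study population only reports correlations of its volume ratios, not the
ratios' range. With the default geometry the resulting brain volume ratios
(about 0.46–0.74) span a wider range than is physiological, which makes
the CSF-shunting mechanism easy to resolve at desk scale; the regressions'
signs, not their magnitudes, are the claims the package makes.

Rasterization uses a center-in rule (a voxel belongs to the innermost shell
containing its center) — unambiguous and orientation-free. Determinism is
bit-exact: identical spec and seed give identical volumes.

## Electrode models

Both models place a rigid 70 × 50 × 3 mm pad tangent to the scalp. The pad
underside is held one nominal gel thickness (default 3 mm) above the
scalp's highest point under the footprint, and the full gap down to the
skin is filled with conductive gel — reproducing the no-gap condition the
segmentation-based pipelines enforce by hand. On a flat slab this yields a
uniform 3 mm gel layer and exactly the intended 35 cm² contact; on a
curved scalp the gel is thicker toward the pad edges, as draped paste is.
A 5 mm option supports the gel-thickness sensitivity analysis
(`analysis/04_gel_thickness.R`); the current-density volumes are nearly
indistinguishable (SSIM ≈ 1, suprathreshold Dice ≈ 0.996 on the default
phantom).

The *artificial* model places pads exactly at the planned anchors — the
frontal bilateral montage analog, defined by polar/azimuth angles chosen so
the idealized short-edge separation on the default head is about 4.7 cm.
Per-subject anchor jitter (tangential Gaussian, SD 5°) is applied
identically to both models, so each subject has their own planned montage.

The *real* model additionally perturbs each pad, all seeded: a systematic
tangential slip away from the partner electrode (default 11 mm — head-coil
pressure and operator error widen montages), isotropic tangential jitter
(SD 4 mm), rotation about the pad normal (SD 10°), and a gel-footprint
area multiplier drawn uniformly from [0.85, 1.35] (hair and coil contact
make paste coverage deviate in either direction). The published study
reports the resulting distributions, not the generative process; these
defaults were calibrated once so the synthetic cohort's separation
distributions land near the published 4.7 ± 1.2 cm (idealized) and
7.15 ± 1.1 cm (as-placed), and the coverage range reproduces the
normalized-area spread 1.12 ± 0.12. One deliberate deviation: the
published SDs put slightly *more* spread in the idealized arm (1.22 vs
1.06 cm), but a generative model in which "real = planned + extra noise"
cannot have less variance in the real arm; the package keeps the variance
ordering (idealized tighter) and matches the published SDs approximately.
Idealized normalized contact areas also come out much tighter (SD < 0.01)
than the published 0.03, because smooth phantoms lack the scalp-topology
variation of segmented heads.

Contact area is measured on the gel–skin interface as cosine-projected
6-connectivity faces (projection onto the pad plane): a raw staircase face
count overestimates curved interfaces by up to ~1.5× and does not converge
under refinement, while the projected count converges to the contact-patch
footprint. Separation distance is the Euclidean distance between the
short-edge midpoints nearest the partner electrode, with an anterior
tie-break; normalized areas divide every contact area by the idealized-
model mean, which forces the idealized mean to 1 identically.

## Reductions and statistics

Regional dose is summarized by the sample median of $|\mathbf{J}|$ (mean
of the central pair for even counts) so electrode-adjacent hotspots do not
skew the summary. ROI analogs are angular sectors of the brain compartment
relative to the inter-electrode midline: stacked superior/middle/inferior
frontal sectors between the electrodes (analogs of the gyri targeted by a
frontal bilateral montage) and a lateral posterior-inferior temporal
sector as the non-target control. FreeSurfer-style anatomical ROIs cannot
be replicated on smooth phantoms; sector bounds are fixed configuration.

Percent difference is always 100·|artificial − real|/real (absolute,
relative to the as-placed model). Paired t-tests use the n−1 sample SD and
a two-sided p from the t distribution via the regularized incomplete beta
function; regressions are ordinary least squares with R² = 1 − SSres/SStot
and a two-sided slope p on n−2 degrees of freedom. Both are cross-checked
against `stats::t.test` and `stats::lm` in the test suite. No
multiple-testing correction is applied anywhere, matching the uncorrected
reporting convention of the comparison this package emulates; voxelwise
paired t-maps are thresholded at p < 0.001 uncorrected on the shared
phantom grid (the phantoms are co-registered by construction, so no
template registration is needed). Voxels with zero difference variance are
excluded and counted. SSIM uses the standard constants (11-voxel window,
K1 = 0.01, K2 = 0.03, dynamic range from the masked maxima); Dice is
computed between suprathreshold sets at a configurable percentile (default
99th) of each volume, a package decision since binarization of continuous
dose volumes has no canonical definition.

## What the workflow shows — and does not

With defaults (96³ voxels at 2 mm, 16 subjects, 32 solves, a few minutes
on one CPU — grid sizes chosen so the full workflow runs at desk scale),
the experiment recovers the comparison's mechanisms:

- as-placed montages are wider and their doses larger; regional medians
  differ by several to tens of percent between models on identical tissue;
- the percent difference in separation distance predicts the percent
  difference in dose (positive, significant), while contact-area
  differences do not;
- median brain/GM/WM dose rises with brain volume ratio in both models
  (less current reaches atrophied brains, the CSF-shunting mechanism);
- the frontal target sector receives more current than the temporal
  control in every subject and model.

Magnitudes of R² and t statistics depend on the synthetic perturbation
scales and are reported, not asserted. Whether the idealized or the
as-placed arm correlates more strongly with atrophy is seed-dependent
here, so the published "slightly larger in the idealized arm" ordering is
not treated as a stable property. Gyral folding, anisotropic white matter,
capacitive effects and real segmentation error are out of scope; passing
tests demonstrate correctness of the solver and the comparison machinery
on phantoms, not fidelity to any individual head.
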