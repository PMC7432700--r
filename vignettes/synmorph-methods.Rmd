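---
title: "Quantitative 3D morphometry of synaptic boutons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative 3D morphometry of synaptic boutons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmorph)
```

## The measurement problem

Serial-section electron microscopy characterises a cortical synaptic bouton
by a handful of structural parameters that are morphological correlates of
synaptic transmission: the bouton's membrane surface area and volume, the
number, size and shape of its active zones (AZs, each composed of a
presynaptic density, PreAZ, and a postsynaptic density, PSD), the synaptic
cleft width, and the sizes of three functionally defined vesicle pools — the
readily releasable pool (RRP), the recycling pool (RP) and the resting pool.
All of these are derived from per-section manual annotations: closed
contours for membranes and organelles, short polylines for the electron
dense membrane specialisations, and point marks for vesicles.

`synmorph` implements this measurement chain — alignment, contour-stack 3D
reconstruction, AZ metrics, perimeter-based pool classification and the
standard statistics — together with a ground-truth scene generator that
emulates both observation modalities (55 nm serial sections, and anisotropic
5 x 5 x 50 nm voxel sampling typical of focused-ion-beam scanning EM). Every
stage can therefore be validated against known geometry, which is impossible
with real annotations.

## The synthetic scene model

A scene is a deterministic function of a `scene_params()` object (including
its seed). Its components:

**Bouton membrane.** A star-shaped radial surface `x(u) = r(u) u` about the
bouton centre. The base is a triaxial spheroid — flattened along one
in-plane axis and mildly elongated along the cutting axis — modulated by a
few dozen smooth outward lobes. Two observations motivate this family.
First, published human neocortical values imply surface-to-volume ratios
near 10 µm^-1; a body with those measurements must be locally thin
(mean local thickness 2V/S ≈ 200 nm), i.e. sheet-like rather than globular,
so the flattening parameter is solved by bisection until the meshed shape
family matches the configured surface-area and volume targets
simultaneously (a global scale factor then pins both exactly). Second, the
lobes are kept wide (Gaussian half-width ≈ 0.25 rad, about 100–150 nm)
deliberately: surface structure finer than the 50–60 nm section pitch could
never be recovered by contour lofting, so roughness below that scale would
make the ground truth unmeasurable by construction rather than by biology.
Lobes point outward only, leaving the spheroid core free for organelles, and
the lobe field is damped near the poles (so every cross-section stays
star-shaped about the axis) and suppressed around the AZ directions (the
synaptic apposition is smooth in EM).

**Active zones.** Each AZ direction is drawn near the flat faces of the
bouton; the PreAZ is the set of membrane mesh faces within a chord radius of
the patch centre, with the radius solved so the realised patch area matches
its target to about 0.3%. Shape classes are angular masks on the patch:
macular (full patch), ring (annulus, inner radius 0.55 of the outer),
horseshoe (annulus with a 120 degree opening) and perforated (two interior
holes of 0.2 relative radius). The PSD is the patch offset outward along
local membrane normals by the cleft-gap field — central width at the patch
centre grading linearly to the lateral width at the rim, plus per-vertex
Gaussian noise — so the two membrane specialisations are parallel by
construction and the contour-length-ratio PSD estimator can be tested
against a known truth.

**Mitochondria.** Slab-shaped ellipsoids matched to the flattened interior
(thin along the flat axis, spread along the wide axes), stacked along the
cutting axis in up to three lanes, with girths adapted to the local calibre
and lengths following from the volume budget. The total mitochondrial volume
realises the configured fraction of bouton volume (default 0.15, inside the
10–20% range typical of cortical boutons) to within ±0.02; if a slab cannot
be placed, its remainder is carried to the next one, and a genuinely
infeasible configuration raises an error naming the binding constraint.

**Vesicles.** The perimeter p of a vesicle is its minimal distance to the
nearest PreAZ patch minus its radius. Pool bins follow the field's edge
table: p <= 10 nm (strict RRP), 10 < p <= 20 (loose RRP), 20 < p < 60
(an unnamed intermediate bin, labelled explicitly rather than folded into a
named pool), 60 <= p <= 200 (RP) and p > 200 nm (resting). Integer bin
counts are exact by construction: the named bins are rounded to the nearest
integer from the configured fractions and the intermediate bin absorbs the
remainder. Docked vesicles (a configurable fraction of the strict RRP) are
placed in membrane contact (p = 0) on the patch. All other vesicles occupy
sites of a jittered close-packed lattice (site spacing = smallest diameter
plus tolerance): each site's admissible radius is capped by its
already-occupied neighbours, which makes non-overlap exact, and the site's
exhaustively computed patch distance decides which bins it can serve. The
lattice is the only placement scheme we found that reaches the packing
densities the published counts imply (~1800 vesicles in 0.16 µm^3 is about a
quarter of the bouton volume in vesicles) — random sequential insertion
jams well below that. Vesicle diameters are drawn uniformly from 30–40 nm
subject to the local caps. Ground-truth labels are validated per scene by
recomputing every perimeter with exhaustive point-to-triangle distance.
The distance ground truth uses a moderately coarsened triangulation of the
same smooth patch; its chordal deviation from the fine surface is below
1 nm at these curvatures. Because dense draws occasionally produce an
unpackable geometry, the constructor retries the stochastic build a few
times (deterministically derived sub-seeds) before declaring infeasibility.

The resting pool's distance distribution is not constrained by published
data beyond "beyond 200 nm"; sites are occupied uniformly, i.e. a truncated
uniform spatial distribution, which is a modelling choice, not an empirical
claim.

**Dense-core vesicles.** A few large (70–90 nm) vesicles placed away from
the AZ, mutually separated by at least 250 nm so that the de-duplication
rule (keep the largest-profile appearance across adjacent sections) can be
tested against exact track counts.

## Observation models

**Serial sections (TEM mode).** Sections are half-open slabs
`[z_lo, z_hi)`; a sphere tangent to a boundary plane belongs to the lower
section. Nominal thickness 55 nm with uniform ±5 nm jitter; optional
per-section translation noise (alignment is translation-only, matching the
linear alignment of standard workflows) and section loss, retained as
explicit gaps. Contours are traced at <= 5 nm vertex spacing. Density
polylines are drawn on the membrane (offset 0 by default; an inward offset
is configurable) — if the trace were offset inward, every measured vesicle
perimeter would be biased by that offset relative to the geometric truth.
A vesicle appears as a mark in every section its sphere intersects, with
measured diameter equal to the projected profile through the slab
(`2 sqrt(r^2 - d^2)`, d the distance from the centre to the slab). The
pipeline follows the annotator's convention of one mark per vesicle by
keeping the largest-profile appearance (`primary_marks()`).

**Voxel volumes (FIB-SEM mode).** Centre-point membership labelling at
5 x 5 x 50 nm (default) or isotropic 5 nm pitch, stored sparsely. The
vesicle detector is deliberately simple — 6-connected components — because
its purpose is to measure the partial-volume bias of anisotropic sampling:
at 50 nm z pitch, adjacent vesicles merge and thin vesicles vanish, so
anisotropic counts are at or below isotropic counts; this ordering is the
tested property.

## Measurement chain

* `align_stack()` estimates one in-plane translation per section from
  matched bouton-contour centroids (500 nm gate), which is exact for
  symmetric objects and recovers injected shifts to well under 2 nm RMS.
* `cavalieri_volume()` is the primary volume estimator (contour area times
  realised thickness, summed), robust to lost sections; the divergence
  theorem volume of the lofted mesh serves as a cross-check.
* `loft_surface()` stitches consecutive contours (common resampling,
  rotational registration, shortest-diagonal triangulation, capped ends).
  Lost-section gaps wider than `max_gap` mark the model truncated rather
  than being bridged.
* `extract_preaz()` implements the strict apposition rule: a membrane mesh
  triangle belongs to the PreAZ iff its in-plane distance to the section's
  density trace is strictly less than 30 nm. `estimate_psd_area()` is the
  contour-length-ratio estimator `SA_PSD = SA_PreAZ x l_PSD / l_PreAZ`,
  exact when the specialisations are parallel; on our parallel-membrane
  scenes its residual bias is the cleft-to-curvature ratio (a few percent).
* `measure_cleft_stack()` measures the cleft at the two lateral edges and
  the centre of the density in the AZ's central section, averages the
  laterals, and excludes profiles whose apposition direction leaves the
  section plane (obliquely cut AZs), mirroring the perpendicularity filter
  of the published protocol.
* `vesicle_perimeter()` measures the centre distance in plane within the
  mark's own section (the per-section protocol). Marks in sections without
  any density trace — typically resting-pool vesicles far from the AZ in z —
  fall back to the cross-section distance (minimum over sections of
  `sqrt(inplane^2 + dz^2)`) and are flagged; without the fallback most of
  the resting pool would be unmeasurable. A full `"3d"` mode exists for
  comparison.
* `classify_pools()`, `count_docked()` and `dedup_dense_core()` implement
  the edge-table binning (cumulative p20, conservation, docked <= p10),
  and the largest-profile de-duplication for dense-core vesicles; small
  clear vesicles receive no multi-section correction, per the published
  protocol.
* `aggregate_subjects()` is the two-level mean: within-subject means first,
  then an unweighted mean ± SD across subjects. `kruskal_posthoc()` wraps
  the tie-corrected Kruskal–Wallis H with two-sided Mann–Whitney U tests
  per pair; multiplicity adjustment is Bonferroni by default (the published
  protocol names post-hoc U tests without an adjustment; the choice is
  configurable and logged).

## Presets and problem sizes

`scene_preset("L4_TLN")` and `scene_preset("L5_TLN")` encode representative
published layer means for adult human temporal lobe neocortex: surface area
2.50 / 6.09 µm^2, volume 0.16 / 0.63 µm^3, PreAZ area 0.13 / 0.23 µm^2,
cleft lateral/central widths 14.11/16.47 and 17.24/19.05 nm, and total
vesicle complements 1821 / 1519 with pool means (p10, p20, RP, resting) of
(20, 49, 382, 1252) and (5, 15, 182, 1264). Pool fractions are the pool
means over the total mean; with the preset totals the rounding scheme
reproduces the published integer counts exactly.

Default problem sizes in the test-suite and the acceptance script are
chosen so a full run stays within a few minutes on one core: recovery runs
use 8–20 preset scenes, the null-calibration uses 1000–2000 simulations,
and the modality comparison uses ~300-vesicle scenes. These sizes give
Monte-Carlo errors comfortably below the tolerances they are tested
against.

## What the generator does and does not emulate

The generator reproduces the geometry the measurement chain sees: section
thickness jitter, misalignment, section loss, the annotation conventions
(density traces, one mark per vesicle at its largest profile), anisotropic
voxel sampling, and realistic parameter ranges. It does not render EM
texture, noise or membrane-contrast ambiguity, so passing tests demonstrate
the correctness of the measurement chain given faithful annotations, not
robustness to segmentation error. Tomographic tilt-series reconstruction,
astrocytic ensheathment geometry and molecular substructure are out of
scope.

## Numerical choices and degenerate inputs

* Coordinates are nm throughout; areas and volumes convert to µm^2 / µm^3
  only at the reporting layer.
* Closed polygons repeat their first vertex; orientation is normalised
  counter-clockwise; unclosed contours are an error for volume estimation.
* A vesicle overlapping the density (negative perimeter) is clamped to
  p = 0 and counted in the strict RRP — physically it is touching.
* Distance to a density polyline uses the nearest point on the polyline
  (including endpoints), not the perpendicular foot only.
* The horseshoe/macular boundary is a convex-hull area deficit of 0.28 on
  the rasterised patch (16 nm cells) — rasterised macular patches sit near
  0 and horseshoes near 0.35–0.45, so the boundary separates the classes
  with wide margins; ring requires a single hole covering at least 20% of
  the outline. These thresholds are package conventions — the literature
  states no criterion.
* Pool-bin proposal guards keep generated perimeters 0.5–1 nm away from the
  bin edges so that discretisation cannot flip a ground-truth label.
* `kruskal_posthoc()` uses the normal approximation with continuity
  correction in the U tests (groups here are far above exact-test sizes).
* Degenerate inputs error early and by name: zero-height scenes, spacing
  larger than the scene, `l_preaz = 0`, groups with fewer than two values,
  unmatchable consecutive sections.

## Known limitations

* Lofted surface areas of strongly lobed boutons are biased low by a few
  percent relative to the fine-mesh truth (features near the section pitch
  are partially smoothed); Cavalieri volumes are unaffected.
* The strict 30 nm apposition rule includes membrane up to ~28 nm beyond the
  ends of the density traces, so rule-measured PreAZ areas carry a positive
  rim bias of roughly 10-15% relative to the geometric density patch at
  typical patch sizes (and holes narrower than ~60 nm are bridged). This is
  a property of the published measurement rule itself, visible here only
  because the geometric truth is known.
* The per-section perimeter is an upper bound on the 3D distance within a
  section; with 55 nm sections the induced pool-fraction bias is well
  inside the ±0.03 recovery tolerance, dominated by vesicles near bin
  edges.
* The lattice packing slightly skews realised vesicle diameters below the
  uniform 30–40 nm draw wherever neighbours crowd (dense scenes), because
  site caps truncate the upper tail.
* Alignment is translation-only; rotational misalignment is not modelled.
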