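---
title: "Planning two fixation screws in the distal acromion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning two fixation screws in the distal acromion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acroplan)
```

## The problem

Fractures of the anatomic acromion (Ogawa type I) are increasingly fixed
with two parallel screws driven along the long axis of the distal
acromion. The bone there is a thin, curved plate: a screw that is too
wide, too long, or badly aimed breaches cortex. Surgical planning on a 3D
CT reconstruction answers four questions per patient: the viewing axis
along which the intraosseous corridor is largest, the maximal diameter and
bicortical length of each of the two screws, where their entry points sit
relative to palpable landmarks (the acromioclavicular facet and the
anterior edge), and the screw angles relative to the superior surface of
the distal acromion.

`acroplan` turns that manual, rendering-based procedure into a
deterministic, testable computation on a watertight surface mesh.

## The corridor model

All geometry reduces to parallel-ray queries. For a candidate viewing
direction $d$ we build an orthonormal frame $(u, v, d)$ — $u$ is the
superior reference direction projected orthogonal to $d$, so "up" in the
image is reproducibly superior — and cast one ray per pixel of a grid on
the plane orthogonal to $d$. A watertight, consistently oriented mesh
gives each ray an even number of crossings, hence a set of disjoint
in-bone intervals.

A pixel is **safe** when its ray traverses *exactly one* continuous
in-bone segment whose chord is at least `min_chord` (default 10 mm). One
interval means a screw on that ray stays inside bone for its whole course;
two or more intervals mean the ray exits and re-enters cortex — a breach
path. This is the computed analogue of the oval one sees when rendering
the bone semi-transparent down the acromion axis.

Numerical details that matter:

* **Grazing rays.** A ray passing within $10^{-8}$ (barycentric) of a
  triangle edge, or collecting an odd crossing count, is re-cast with
  deterministic sub-pixel offsets (4 attempts, $\le$ spacing/100); pixels
  still marginal are flagged unresolved and treated as unsafe. This is
  conservative in the direction surgery wants.
* **Solid bone assumption.** The mesh is treated as a filled solid
  (cortex plus trabecular interior), which is what threshold plus
  region-growing segmentation produces. Hollow-shell meshes must be
  voxel-filled first.
* The study population this mirrors used right scapulae only; left-sided
  meshes must be mirrored by the caller.

## Choosing the viewing direction

The manual procedure rotates the model until the translucent oval looks
largest. Formalizing that as "maximize the safe area" fails in an
instructive way: for a convex rod of length $L$, tilting the view by
$\theta$ *adds* a band of obliquely traversing pixels of width
$\sim (L - \texttt{min\_chord})\sin\theta$ per side while the aligned
region shrinks only as $L\sin\theta$, so whenever
$\texttt{min\_chord} < L/2$ the raw safe area is maximized *off*-axis. A
per-map relative threshold (chord above a fraction of that map's maximum)
fails differently: a side view has uniformly short chords and renormalizes
to itself.

The objective that matches the visual criterion — rotate until the entry
and exit outlines coincide — is the area of pixels whose chord reaches a
fixed fraction (`align_frac`, default 0.75) of the *longest chord seen
anywhere in the search cone*. The threshold is frozen after the coarse
sweep, so all candidate directions compete on one scale; per 1D slice of a
rod the qualifying width then changes as $-(2f-1)L\,\theta$, which is
strictly decreasing in the misalignment for any $f > 0.5$. On an extruded
elliptic rod the search recovers the axis to 0.25° from a 10°-off start.

The search itself is a coarse spherical grid (3° steps) inside a cone
(default half-angle 30°) around an anatomical initialization — the
principal direction of the superior landmark patch, oriented posteriorly —
followed by deterministic pattern-search refinement to 0.5°. The cone
restriction is deliberate: a full-sphere optimum could be clinically
meaningless. Areas are averaged over two half-pixel-shifted grids to
suppress pixel-quantization noise near the optimum.

## From corridor to screws

The **zone** handed to screw fitting is the largest 8-connected component
of pixels above the *alignment* threshold — the long-chord oval the screws
actually occupy — traced to a sub-pixel polygon; `min_chord` remains the
hard safety floor in the safe flag. The zone is split by a line
perpendicular to its major principal axis, positioned by bisection so the
two halves have exactly equal area ("divided evenly"; a centroid line
alone does not bisect asymmetric regions). The half nearer the projected
AC facet is the medial one.

Each half is then refined to the pixels whose in-bone interval **covers**
the screw's axial span (probed at the half's inscribed center): a pixel
with a long chord elsewhere along the ray is useless to a screw crossing
the whole corridor. The maximal inscribed circle of the refined half
(distance-field grid search plus simplex polish, accurate to about
0.05 mm) gives the screw axis and radius; ties break toward the smallest
$(u, v)$ center.

Screw length is the full in-bone chord at the axis — entry at the near
(anterior) cortex, tip flush with the far cortex, the bicortical
"just-penetrating" rule. Containment of the cylinder inside the solid is
verified by sampling the lateral surface (24+ angles, axial stations every
1.25 mm, 0.05 mm inside the nominal radius); failures shrink the radius in
0.05 mm steps (at most 10). The end regions — max(1 mm, 1.5 radii) at each
cortex — are exempt: where the far cortex crosses the axis obliquely, a
tip that just penetrates it necessarily protrudes on one side, exactly as
a clinical bicortical screw does. By default the two maximal screws may
touch (`clearance = 0`): the inscribed circles of a split disc are
mutually tangent, and the reference procedure lets screws reach the zone
border; a positive clearance shrinks both radii proportionally.

## Measurements

* **L1–L4**: straight-line 3D distances from the medial (L1, L2) and
  lateral (L3, L4) entry points to the AC facet point and the anterior
  edge point. The facet is a single representative point (caliper-style);
  point-to-patch distance would also be defensible, and the choice is
  isolated in `landmark_distances()`.
* **Plane A** is the total-least-squares plane of the superior patch
  vertices, normal oriented superiorly. The downdip **α** is
  $90°$ minus the angle between the screw direction and the normal.
* **Plane B** is perpendicular to plane A through the zone centroid. Its
  free azimuth must be pinned: pinning it to the *optimized* corridor
  direction would make the inclination **β** identically zero, since the
  screws are parallel to that direction and any plane containing a line's
  projection and the normal contains the line. We pin it instead to the
  anatomical long-axis reference (the landmark initialization), so β
  measures the medial/lateral deviation of the planned course from the
  anatomical axis — which is what the inclination figure in the source
  procedure depicts.

Both screws share one direction, so each subject reports a single (α, β)
pair. All measurement operations are rigid-motion invariant to $10^{-6}$.

## The synthetic anatomy

No imaging data accompanies the reference study, so validation runs on a
parametric stand-in with exact ground truth. One swept-solid builder
produces every shape: an elliptical cross-section $a(z) \times b(z)$
($a$ = half-width, $b$ = half-thickness — the "canal" semi-axis that caps
screw diameter) extruded from the anterior tip, with

* a linear taper (default 0.88 at the posterior end);
* an oblique posterior end cut (`end_slope`, default 0.85 mm/mm): the
  medial side runs on into the scapular spine, making the medial screw
  ~5–7 mm longer than the lateral one, as in the reference tables;
* a flattened superior strip (depth 0.14 of the local half-thickness over
  2–12 mm from the tip, tilted slightly *upward* posteriorly) — the patch
  plane A is fitted on;
* smooth low-frequency sinusoidal surface bumps (default 0.12 mm; white
  noise would break watertightness and realism);
* a circular-arc bend of the whole rod (default 10° total) about an
  oblique horizontal axis (default azimuth 40°, mixing inferior with
  medial curvature). The bend is applied by an exact map with an exact
  inverse, so the generator returns an analytic `inside()` predicate for
  the *same* solid — the independent oracle the test-suite ray-marches.

Ground truth per subject: the centerline chord (ideal corridor axis), the
distal tangent (anatomical axis), the analytic normal of the bent flat
strip, and the implied α and β.

The default cohort draws per-sex tip semi-axes and rod lengths (male
$b \sim N(2.9, 0.4)$, length $\sim N(51, 4)$; female $b \sim N(2.0,
0.3)$, length $\sim N(42, 4)$; truncated at 3 SD), shared shape
parameters, and one mesh seed per subject from the master seed. These are
constructed distributions, not data from any patient cohort. Pipeline
lengths land on the reference-table magnitudes; pipeline *diameters* land
1.5–2 mm below them, because the curvature sag and the superior facet cut
shave the full-span corridor below the $2b$ ceiling the simple half-zone
picture suggests — the sex contrast (the tested property) is unaffected.
Passing these tests shows the pipeline recovers known geometry and known
group differences; it does not certify behaviour on features the generator
lacks (cortical thinning, osteophytes, the full scapular body occluding
oblique views, segmentation noise).

A handful of subjects per hundred (more among small-boned females) admit
no two-screw corridor at the 2 mm minimum diameter; the cohort runner logs
and excludes them, aborting only above 20% failures.

## Problem sizes and runtime

Default grids: 0.25 mm pixels for single-subject maps, 0.5 mm for the
search and for cohort runs; the mesh resolution is 40 sections × 48 rings.
With these choices one subject plans in 1–2 s, the 100-subject cohort
study in ~2 min, and the null-cohort calibration (100 replicate cohorts of
3 + 3 subjects at a 0.75 mm screening grid with a 15° cone) in ~4 min.
The null study draws both "sexes" from one distribution and checks that
the sex comparison stays at its nominal level — the pipeline must not
fabricate differences.

## Known limitations

* The corridor direction is shared by both screws; independent per-screw
  angulation is not modeled.
* Fracture lines, bone density, thread purchase, and hardware geometry
  (threads, cannulation) are out of scope: the plan is purely geometric.
* Volume input uses boundary voxel-face extraction: watertight by
  construction and volume-exact, but stair-stepped; optional Taubin
  smoothing relaxes the staircase at a small cost in volume fidelity.
* Whether the two screws of the reference procedure were constrained to
  equal diameters is not stated there; each half is fitted independently
  here.
* L1–L4 are 3D Euclidean distances; surface (geodesic) distances would
  differ on strongly curved bone.
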