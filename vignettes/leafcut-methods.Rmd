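---
title: "From confocal leaf stacks to cell morphometrics: the methods behind leafcut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From confocal leaf stacks to cell morphometrics: the methods behind leafcut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafcut)
```

## The problem

Cereal leaf epidermis is organised in longitudinal cell rows whose
geometry (cell sizes, shapes, neighbour relations) encodes the history of
growth and cell-fate decisions — stomatal rows, trichome rows, pavement
cells. Confocal stacks of stained leaves image the cell-wall network in
one channel and nuclei in another, but the leaf surface is curved: no
single z-slice shows the epidermal cell pattern. Full 3D segmentation is
fragile here because the *outer* periclinal wall fluoresces much brighter
than deeper walls, and because trichomes rise above the blade and shadow
it.

`leafcut` flattens the problem instead of fighting it. It detects the
leaf surface per (x, y) position, samples the stack a fixed distance
below that surface ("virtual cut"), segments the resulting 2D wall image
with a marker-controlled watershed, and measures every cell. Nuclei are
segmented in 3D and matched to cells through a cylinder approximation of
the epidermal layer.

## Surface detection and the virtual cut

For every (x, y) position a *virtual puncture* runs along z and records
the slice of maximal wall-channel intensity. Because the outer wall is
the brightest structure along almost every puncture, these maxima trace
the leaf surface; ties resolve to the smallest z (slice 1 is the
objective side by convention, with a `flip_z` reader flag for stacks
acquired the other way). Punctures whose maximum stays below
`min_intensity` carry no surface information (deep shadow, tears) and are
filled from the nearest valid puncture before a median filter (default
radius 2 px; a mean filter is available) produces the smooth "surface
approximation". The median is the default because argmax outliers are
impulsive, not Gaussian.

The virtual cut samples intensity at `z_surface + depth` with linear
interpolation along z and clamping at the deepest slice. `depth` is
expressed in slices (fractional allowed; divide micrometres by the slice
spacing `dz` to convert) and defaults to 2 slices — deep enough to leave
the bright periclinal sheet, shallow enough that anticlinal walls still
carry signal.

Trichomes appear in the z-map as protrusions toward smaller z. They are
removed on the *mask*, not the intensity volume: grayscale closing with a
disk (default radius 5 px) flattens any protrusion whose base radius is
smaller than the disk, after which the cut is re-extracted. Closing is
idempotent, so repeated application is safe.

## Denoising

The denoiser is the explicit Perona–Malik scheme: flux between
4-neighbours (6 in 3D) weighted by a conductance
`g = exp(-(|grad| / kappa)^2)` (or the rational variant). Gradients well
below `kappa` diffuse; gradients above it — cell walls, nucleus rims —
are preserved. Defaults: 10 iterations, `kappa = 30` on an 8-bit scale
(the pipeline rescales it by the actual intensity range), time step
`gamma = 0.2` in 2D and 0.15 in 3D, inside the stability bounds 1/4 and
1/6. The scheme is flux-conservative with reflecting boundaries, so the
image mean is conserved and the extremum principle holds — both are
tested, as is convergence to the closed-form linear heat evolution when
`kappa` is enormous. 3D diffusion scales z-gradients by `dz/dx` so the
anisotropic slice spacing does not over-couple slices; the pipeline
defaults to per-slice 2D filtering, which is faster and sufficient ahead
of a 2D cut.

## Segmentation

Both cell and nucleus segmentation use one engine: a Meyer-style
priority-flood watershed from markers, producing basins indexed 2..K+1
and explicit 1-px watershed lines with the reserved value 1 (0 is
background) — the label encoding used in all outputs. Markers are the
regional minima of the h-minima transform of the relief: minima shallower
than `dynamic_tolerance` are filled and never seed a region. In *border*
mode (cell walls) the image itself is the relief; in *object* mode
(nuclei) the inverted image is flooded, pixels below
`background_threshold` are excluded, and regions smaller than `min_size`
voxels are dropped — the staining protocol requires nuclei to span at
least 3 px in diameter, so smaller blobs are sub-resolution debris by
construction. Basin order is deterministic (row-major position of each
marker's first pixel), so segmentations are reproducible byte for byte.

Region connectivity defaults to 4 (2D) / 6 (3D) so that 8-/26-connected
thin lines can separate regions; the suite verifies that deleting the
lines and re-labelling by connectivity reproduces the same partition.

Label editing is programmatic rather than interactive: `merge_labels`
(adjacent groups only, separator absorbed), `remove_label` (exclusive
boundary cleared, shared lines kept), `group_labels` (annotations such as
row membership that surface in the feature table), and
`heal_fragmented_labels`, which merges regions separated by a boundary
exactly one pixel wide — the signature of an over-split nucleus — and
iterates to a fixpoint without ever crossing wider separations.

## Morphometrics

Outlines are traced as crack-boundary polygons (along pixel edges) and
simplified by Ramer–Douglas–Peucker with a 1-px tolerance. The crack
polygon is exact for axis-aligned shapes (a 20x20 square keeps perimeter
80), and the sub-pixel simplification collapses the rasterisation
staircase on curved outlines (a digital disk of radius 30 recovers the
true circle perimeter to ~1%). Midpoint iso-contours were rejected: they
chamfer right-angle corners and bias square perimeters low. The same
polygon feeds perimeter, convex hull, lobeyness and the oriented bounding
rectangle, keeping the features mutually consistent.

Per cell the package reports, in physical units: area (pixel count x
`dy*dx`); perimeter; best-fit-ellipse length and width (from
pixel-extent-corrected second moments, so a 40x10 rectangle yields an
axis ratio of exactly 4); elongation `1 - W/L`; circularity
`2*sqrt(pi*A)/P` (equivalent-disk perimeter over perimeter);
rectangularity (area over the minimal-area *oriented* rectangle, found by
rotating calipers — cells lie at arbitrary angles, so the axis-aligned
box would be orientation-biased); and lobeyness, the convex-hull
perimeter over the cell perimeter: 1 for convex cells, markedly lower for
wavy, jigsaw-puzzle pavement cells. The field also uses the inverse
ratio under the same name; this package fixes the hull/perimeter form,
for which values are always ≤ 1.

Neighbour counting treats two regions as adjacent when any pixel holds
both within its 8-neighbourhood (so 1-px watershed lines do not hide
contacts). Cells touching the image border are flagged marginal: they
count as neighbours of interior cells but should be excluded as analysis
subjects, since part of their own neighbourhood is unobserved.

Guard-mother-cell screening builds on two observations: GMCs typically
have exactly four neighbours (two in-row sisters, one cell in each
abutting row), and they arise from an asymmetric division, so the cell
size index `M/(M+S)` against the left in-row sister is well below 0.5 —
candidates above 0.5 are flagged as likely trichome precursors instead.
"Left" is the in-row neighbour (|across-axis offset| < |along-axis
offset|) on the smaller-coordinate side of the growth axis (x by
default, configurable).

Volumes: 3D regions are voxel count x `dz*dy*dx`. 2D-segmented cells get
a cylinder volume `area x epidermal depth`. A nucleus is matched to the
cell whose label sits under its XY centroid, provided its z-centroid lies
within the cell's cylinder window `[z_surface, z_surface + depth]`; when
several nuclei compete for one cylinder the one with most voxels inside
wins and the rest are reported unmatched, as are nucleus-free cells.
The epidermal depth has no universal value — it is a per-dataset
parameter (default 8 slices in the pipeline configuration).

## The synthetic phantom: what it does and does not emulate

Real validation data with known per-cell truth do not exist at desk
scale, so the package ships a generator whose defaults *are* the study
conditions of the test suite: a 24 x 128 x 192 voxel stack at
1 x 0.5 x 0.5 um, a smooth sinusoidal surface (base slice 10, amplitude
3 slices by default, up to 5 in the surface-recovery tests), a brick
("rows", 5 x 8 = 40 cells) or Voronoi ("puzzle") tessellation, 3-px
anticlinal walls painted from the surface down 6 slices with intensity
decaying linearly to 40% (the outer wall images brightest) and a peaked
transverse profile (walls are brightest at their midline), a continuous
outer periclinal sheet at 120 vs. ridge 220 (the surface-mask premise:
every puncture peaks at the surface), one ellipsoidal nucleus of radius
4 px per cell centred 4 slices below the surface, optional trichome cones
rising toward smaller z, then optional Poisson shot noise and Gaussian
read noise before integer quantisation (so stack I/O can be bit-exact,
as for a real detector). "SNR 5" in the tests means read-noise sd 44
against the 220 ridge. The 3-px wall and >= 3-px nucleus diameter
minima mirror the imaging protocol's resolvability rule and are enforced.

The phantom deliberately omits: a realistic PSF (no z-elongated blur),
wavy anticlinal walls (cells are polygonal, so phantom lobeyness is ~1 —
lobeyness accuracy is instead tested against exact polygon geometry and
an arc-length oracle on sinusoidally lobed outlines), intensity
attenuation with depth, and multi-valued (folded) surfaces. Passing the
suite therefore demonstrates the machinery is correct under the stated
image model, not that segmentation will succeed on arbitrary real
acquisitions — tolerances on real data are set through the configuration.

One subtlety in the lobed-polygon family `r(theta) = R + A sin(k theta)`:
below `A = R/(k^2 - 1)` the outline is still convex and lobeyness is
exactly 1, so the strict-monotonicity checks start at `A = 0.1 R`.

## Numerical choices and degenerate inputs

Ties in the puncture argmax go to the outermost slice. The watershed
priority queue breaks equal-priority ties first-in-first-out, making
plateau assignment deterministic. Region indices are compacted to 2..K+1
after any size filtering. Median/mean surface filters use clipped
windows at image borders; diffusion uses reflecting boundaries. CSV
output fixes 6 significant digits with a `.` decimal separator regardless
of locale. Degenerate inputs error early with the offending argument
named: zero-area polygons, empty surfaces (no puncture above threshold),
zero markers (with the advice to lower the tolerance), non-adjacent merge
sets, absent label ids, gamma outside the stability bound.

Problem sizes in the tests and the acceptance script (10-20 phantoms of
24 x 96 x 128 to 24 x 160 x 320 voxels) were chosen so the full suite
exercises every stage, including 20-seed noisy replicates, in about a
minute of compute; all quantities they check are scale-free (RMSE in
slices, IoU, rates), so larger stacks change runtime, not the contracts.

## Known limitations

Multi-valued surfaces (folded leaves) are out of scope, as is 3D mesh
reconstruction of the surface; the surface is a single-valued height
map. Offset refinement in stitching is integer-pixel (cell-scale
analysis does not need sub-pixel registration). The GMC left-sister rule
assumes rows run along one image axis; strongly curved rows need the
`group_labels` route with expert row assignments. PCA/clustering of the
exported features is intentionally left to the user's statistics
environment — the package's product is the feature table.
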