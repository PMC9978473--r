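---
title: "Slice-plane postprocessing and evaluation of lymph node level segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-plane postprocessing and evaluation of lymph node level segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levelpost)
```

## The problem

Head-and-neck nodal clinical target volumes are built from ~20 lymph node
levels. These are not organs with visible boundaries but conventional
compartments, and one of the conventions is geometric: levels that are
craniocaudally adjacent by definition (level II ends where level III
begins) must meet exactly between CT slices. A 3D segmentation network sees
a resampled volume, not the acquisition slice grid, so its predictions
routinely place voxels of two such levels on the same axial slice.
Clinicians reviewing contours penalise this readily, while bulk-overlap
metrics such as volumetric Dice barely move — the misplaced voxels are a
tiny fraction of each level's volume and the pooled foreground is often
unchanged entirely. `levelpost` implements the postprocessing that repairs
these defects, the metrics and paired statistics used to evaluate
segmentations, the blinded-rating design used to measure what the metrics
miss, and a synthetic phantom that reproduces the defect classes so all of
it can be tested end to end without clinical data.

## Level taxonomy

All operations are driven by a `level_taxonomy`: per level a name, integer
label value and laterality; left/right mirror pairs; and *exclusivity
chains*, ordered cranial→caudal lists of levels that may never share a
slice. The shipped default has 20 levels (midline Ia, VIa, VIb, VIIa;
bilateral Ib, II, III, IVa, IVb, V, VIIb, VIII), i.e. 21 prediction classes
including background, with label values 1–20 assigned contiguously in that
order — a documented artifact convention chosen for interoperability, not
an anatomical fact. Which level pairs count as craniocaudally adjacent is
itself a delineation-guideline convention with room for local
interpretation, so the default chains — the per-side jugular axis
II → III → IVa → IVb — are deliberately conservative and fully
user-configurable in the JSON file. Voxel indices follow R's 1-based array
convention throughout; every physical distance is computed via the voxel
spacing carried by the volume, so no 0-vs-1-based ambiguity can reach a
result.

## Slice-plane adjustment

`slice_plane_adjust()` composes two steps, in a fixed order for
reproducibility (conflict resolution first; it does not change per-slice
foreground totals, so the trim decisions are identical either way):

1. **Within-chain conflict resolution** (`resolve_slice_conflicts()`).
   Iterating slices cranial→caudal, for each chain with ≥ 2 members present
   on a slice, the member with the most voxels on that slice wins and the
   others are relabelled to it. "Area" is voxel count per slice — with
   uniform in-plane spacing the two are equivalent, and voxel count is what
   the network actually predicted. Ties go to the more cranial member,
   which is deterministic and order-independent. The step only relabels:
   total foreground is conserved, and labels outside every chain are
   bitwise untouched.
2. **Boundary-slice trimming** (`trim_boundary_slices()`). Working inward
   from each end of the foreground extent, a slice is reset to background
   if (a) it has `min_foreground_voxels` (default 10) or fewer foreground
   voxels, or (b) its count dropped by `drop_fraction` (default 0.8) or
   more relative to the neighbouring slice nearer the volume centre *and*
   the next slice outward is empty. Each run stops at the first surviving
   slice; all counts are evaluated on the input state, so one pass makes
   one set of decisions.

Two readings of the trim rule were possible: applied to every slice, or
only to the cranial/caudal boundary runs. The stated purpose of the step is
consistency of the *outer* boundaries of the topmost and bottommost levels,
and a global reading would delete legitimate thin interior slices, so the
boundary-run reading is implemented; interior slices are never modified.
The drop rule is likewise applied symmetrically at both ends rather than in
a single scan direction.

On the phantom's count profiles the composed operation is idempotent (the
test suite asserts bitwise equality of one and two applications across 50
seeded phantoms). For adversarial count profiles the trim rule alone is not
a mathematical fixed point — clearing a boundary slice can expose a
neighbour whose outward side is now empty, so a *second* application could
trim further. The one-pass, input-state semantics is kept deliberately: it
matches a single postprocessing pass over a prediction, and repeated
application is not part of the contract.

`keep_largest_component()` implements the standard connected-component
cleanup: per class, only the largest 26-connected component survives.
26-connectivity is the most permissive standard choice and matches common
segmentation practice. Size ties are broken toward the component containing
the lexicographically smallest voxel index, making the operation fully
deterministic.

## Metrics

`evaluate_pair()` reports volumetric Dice, surface Dice and maximum
Hausdorff distance per level, for the union of all levels pooled as one
mask, and as the case mean over defined levels. Decisions worth stating:

* **"One voxel" tolerance under anisotropic spacing.** With 1.14 × 1.14 ×
  3 mm voxels there is no single "one voxel" distance. The default resolves
  it as the *maximum* spacing component (3 mm), the only choice that
  guarantees a one-voxel shift along any axis stays within tolerance; an
  explicit tolerance in mm is available for other conventions.
* **Empty masks.** Empty-vs-nonempty Dice is 0 (an absent level is an
  error, not missing data); empty-vs-empty is undefined (`NA`) and excluded
  from case means, so structures absent from both volumes do not inflate
  results. Hausdorff with an empty mask is undefined.
* **Surface representation.** Boundaries are foreground voxels with a
  6-neighbour background voxel (volume border counts as background), and
  distances are Euclidean distances between boundary voxel centres in mm.
  Surfel-based implementations weight surface elements by area; the
  voxel-centre approximation is the comparability caveat and is what the
  brute-force oracle in the test suite verifies against. Pairwise distances
  are computed from per-axis integer index differences scaled by spacing —
  numerically exact at the knife-edge where a boundary distance equals the
  tolerance, where a Gram-matrix expansion loses the comparison to
  cancellation.

The union-vs-per-level dissociation is structural, not empirical: a
corruption that only swaps labels across a level interface leaves the
pooled mask bitwise unchanged (union Dice exactly 1, Hausdorff 0 mm) while
every affected level's Dice drops. The phantom tests assert exactly this.

## Statistics

The paired signed-rank test enumerates its exact null for n ≤ 25 by shift
convolution over doubled midranks, which remains exact in the presence of
ties (where the classical recursion and most software fall back to a normal
approximation); above n = 25 a normal approximation with tie and continuity
correction is used. Zero differences are dropped — Wilcoxon's original
convention and the default of the major statistics packages — and an
all-zero sample returns p = 1 with a degeneracy flag rather than an error.
The reported statistic is the centred rank sum V − n(n+1)/4, so swapping
conditions negates it. The test suite checks the exact p-values against
full 2^n sign enumeration for every n ≤ 12 and the empirical type-I error
at α = 0.05 over 10,000 null samples of n = 20 (the observed rate, ~0.046,
sits slightly below 0.05 as it must for a discrete exact test).

The "paired robust dispersion test" reported alongside such evaluations is
cited in the literature without formulas; the implementation here is one
published reading: Brown–Forsythe-style absolute deviations from each
condition's median, compared pairwise with the signed-rank procedure. A
pure location shift yields identical deviations and is degenerate by
construction. The rank-sum test for independent groups is standard and
delegates its p-value to `stats::wilcox.test()` (exact when tie-free and
m + n ≤ 20); the reported statistic is the rank sum of the first group. No
multiple-testing correction is applied anywhere — reported p-values are
unadjusted, and summaries use 0.05 as the significance threshold.

`generate_blinded_manifest()` produces the presentation plan for a blinded
rating study: per rater an independent random permutation of all (case,
contour set) pairs, contour-set identities hidden behind aliases (the
alias↔set key is returned separately and is to be kept from raters), one
0–100 rating slot per level per presentation, with the four guidance
categories attached. 3 raters × 20 cases × 20 levels × 3 contour sets gives
the 3600 slots of the design this generator reproduces. Everything is
seeded and bit-reproducible.

## The synthetic phantom

`generate_ground_truth()` builds a deterministic, slice-plane consistent,
exactly mirror-symmetric label volume: per side a column of stacked
elliptical slabs following the exclusivity chain, a second column pair for
the bilateral levels outside the chains, and a midline column. Defaults —
49 × 32 × 36 voxels at 1.14 × 1.14 × 3 mm, 6 slices (18 mm) per level,
disk radius 5 voxels (81-voxel slice area) — were chosen once to mimic the
data regime the method targets: 3 mm slice thickness, ~1.1 mm pixels,
level heights of a few centimetres, per-slice areas comfortably above the
10-voxel trim threshold.

`corrupt()` injects exactly the defect classes the postprocessing targets,
each seeded:

* **Boundary jitter** — on each within-chain interface, voxels of the last
  slice of the upper level and the first slice of the lower level flip to
  the adjacent member with probability `boundary_jitter_prob` (default
  0.1). The default emulates the regime in which slice-plane
  inconsistencies are visually salient yet involve so small a voxel
  fraction that mean volumetric Dice is unchanged to two decimals with or
  without adjustment; at 0.1 the phantom's mean per-level Dice deficit is
  ~0.01, and because the expected flipped fraction per boundary slice is
  far below one half, majority resolution restores the interface exactly.
* **Islands** — small runs of a level outside every chain, placed in
  background, 26-disconnected from all structures and from each other, and
  only within the craniocaudal foreground extent of the truth. The extent
  restriction is generator realism (spurious prediction dots arise near
  structures, not floating above the scan) and keeps the boundary-trim
  rules blind to islands, which are the largest-component step's job.
* **Fringe slices** — beyond each end of the foreground extent,
  `fringe_slices` slices receive `fringe_voxels` (default 6, at or below
  the trim threshold) foreground voxels sampled from the adjacent true
  slice's in-plane positions.

Jitter-only corruption leaves the pooled foreground bitwise unchanged;
fringe/island-only corruption is exactly undone by adjustment plus
largest-component cleanup. Both invariants are asserted across 20 seeded
phantoms each in the test suite, which runs the full property checks
(idempotence, zero residual inconsistencies, voxel conservation) on 50
seeded phantoms in seconds.

`make_intensity_phantom()` supplies the preprocessing test input: a
high-intensity body ellipsoid on low background plus a detached
intermediate-intensity plate imitating immobilisation-mask/mask-holder
remnants. The plate sits above the corrected Otsu threshold, so its removal
genuinely exercises the largest-component step rather than the threshold,
and its gap to the body exceeds the reach of the default width-9 closing
element.

## What the phantom does and does not show

The phantom exercises the algorithms' contracts: conflict resolution,
trimming, component cleanup, mirroring, metric arithmetic, and the
dissociation between union and per-level metrics. It does not emulate real
CNN error structure — no smooth boundary noise, no partial-volume effects,
no anatomically realistic shapes or intensities, no inter-observer
ambiguity. Passing tests therefore demonstrate correctness of the
machinery, not clinical performance; clinical-scale Dice or rating values
cannot be reproduced from synthetic data and are not attempted.

## Numerical and scope notes

* Otsu thresholding uses a fixed 256-bin histogram over the sample range;
  the returned threshold is the bin boundary maximising between-class
  variance, ties toward the lowest boundary. The foreground-masking
  pipeline re-implements a documented approximation (clip → Otsu → scale →
  close → largest component → dilate) of the common interactive-tool
  implementation; parameter names and defaults are preserved for
  comparability, voxel-level agreement with that tool is out of scope. The
  correction factor is read as multiplicative on the threshold.
* The manual cubic ROI crop against anatomical landmarks (skull base,
  carina, humeral heads) requires a human and is exposed only as the
  index-range `crop_volume()` / `levelpost crop` utility.
* Binary morphology uses separable cubic structuring elements; dilation
  treats outside-volume as background, so closing does not erode structures
  touching the volume border.
* Mirrored outputs flip the voxel array and leave the file affine
  unchanged — the output is a training sample, not a clinically oriented
  image.
* Test and acceptance problem sizes (49 × 32 × 36 phantoms, 20–50 seeds,
  10,000 statistical simulations) were chosen as the smallest sizes at
  which every property is non-trivially exercised; all complete in well
  under a minute each on one CPU.
* DICOM / DICOM-RT I/O, image registration, resampling between grids, and
  any coupling to a training loop are out of scope.
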