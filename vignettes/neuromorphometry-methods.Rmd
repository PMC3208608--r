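---
title: "Morphological neurite quantification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological neurite quantification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuritescan)
```

## The measurement model

`neuritescan` measures neuronal morphology per field of view rather than per
cell. In dense cultures the assignment of a neurite to an individual neuron
is often arbitrary even for a trained observer, so the package deliberately
reports field aggregates — each value then summarizes dozens to hundreds of
neurons, which is the regime high-content screens operate in. The cost is
that single-cell arbor statistics (per-cell branch orders, Sholl profiles)
are out of scope by design.

The segmentation is purely morphological. A flat disk structuring element
(SE) sized between a neurite's width and a soma's radius separates the two
structure classes:

* the **greyscale opening** of the image keeps any structure in which the SE
  fits (somata) and levels anything thinner (neurites, debris);
* the **white top-hat** (original minus opening) keeps exactly what the
  opening removed.

Each enhanced image is binarized with a single preset threshold per channel
and experiment. Because thresholds act on morphologically enhanced images,
staining intensity enters only multiplicatively: scaling an image by `k`
with both thresholds co-scaled reproduces every mask bit for bit (this is
asserted as a test invariant, with power-of-two normalization inside
`grey_open()` keeping the float arithmetic exact). Dark-on-light material
(e.g. brightfield images of silver-stained sections) is handled by a plain
intensity complement; no illumination correction is attempted.

After binarization, a size filter removes components below a minimum area.
It labels connected components on the pixel adjacency graph, so specks
*enclosed* by larger objects (inside neurite loops) are removed just like
free-standing ones — flood fills seeded from the border miss those. The
neurite mask is thinned to a one-pixel-wide skeleton and skeleton pixels
over the soma mask are subtracted: total neurite length is the skeleton
pixel count, soma area and counts come from the soma mask.

### Terminals, tips and attachment points

Skeleton terminals (pixels with exactly one 8-neighbour) are partitioned by
a dilated soma zone. A terminal inside the zone is where the skeleton was
severed at a cell body — a **neurite–soma attachment point**, proxying the
number of primary neurites. A terminal outside the zone is a **neurite tip**.
Every terminal is exactly one of the two. This partition is what makes the
branch formula consistent: a connected acyclic arbor with `A` roots and `E`
tips has `E − A` junctions (Euler relation on trees), so
`branch_count = max(E − A, 0)`. An alternative construction — taking the
terminals of the skeleton clipped to the dilated zone — would count the
clip boundary as a second point per neurite and break the "one point per
junction" behaviour, so it was rejected.

The known failure modes follow directly and are preserved on purpose:

* an unattached neurite crossing a soma is cut in two, leaving two cut ends
  near the soma → two spurious attachment points and a skeleton gap;
* tangential contacts and tight V-shaped double attachments leave no
  terminal near the soma → zero attachments rather than one or two;
* disconnected fragments contribute two tips and no attachment → inflated
  branch counts. This is why ratio statistics carry a low-content flag (see
  below).

### Skeleton spur pruning

Two-subiteration thinning (Zhang–Suen class) occasionally leaves one- or
two-pixel nubs at staircase corners, which would masquerade as tips. The
skeletonizer therefore prunes short terminal chains (default ≤ 4 px) — but
only when the local skeleton, with the chain removed, still *runs through*
the junction: within a 9×9 window the junction's component must reach the
window ring at two well-separated places. A zigzag line end presents the
same local degree pattern but fails this test, so genuine tips survive;
genuine branches are vastly longer than the prune depth. Pruning terminal
chains cannot change component or hole counts, so thinning stays
homotopy-preserving (asserted against component/hole-counting oracles).

## Parameters

All lengths and areas are in pixels at the acquisition magnification
(defaults assume ~10×, somata ≈ 18–28 px across); intensities are in the
units of the input bit depth.

| parameter | default | meaning |
|---|---|---|
| `soma_open_radius` | 6 | SE radius of the opening. Must exceed neurite half-width but stay comfortably below the smallest soma radius: an SE close to the soma radius rounds the opened dome and leaves bright top-hat residue around every cell body, which skeletonizes into spurious fragments. |
| `soma_threshold` | 100 | threshold on the opened image |
| `neurite_threshold` | 35 | threshold on the top-hat image |
| `soma_min_area` | 60 | minimum soma component area; kept low because the opening itself already removes small debris |
| `neurite_min_area` | 12 | minimum neurite component area (debris rejection before thinning; applied before skeletonization so thinning never sees specks) |
| `attachment_radius` | 6 | dilation of the soma mask that classifies terminals. The opening suppresses the top-hat where a neurite climbs a soma's intensity skirt, so the skeleton's cut end sits up to ~5 px outside the soma mask; the zone must bridge that without reaching unrelated structures. |
| `reference_soma_area` | 400 | user-defined typical single-soma area (px); divides soma area into an estimated neuron count |

The two thresholds are independent (one per enhanced image) and default to
equal footing with the bundled renderer; `suggest_thresholds()` provides
Otsu-based starting points on representative fields, after which a single
preset pair should be fixed for the whole experiment. Thresholds are
deliberately *not* auto-tuned per image — per-image adaptation would
reintroduce the intensity dependence the morphological route avoids.

Total neurite length is the raw skeleton pixel count; a diagonal-corrected
polygonal length is reported as a secondary column
(`neurite_length_diag`), clearly non-canonical, for users who want a
Euclidean-flavoured measure.

## Derived statistics and undefined values

Ratios are undefined on degenerate fields (no skeleton, no soma). These
become `NA` sentinels, never errors, so one empty well cannot abort a plate.
Fields whose skeleton length or soma area falls below configurable floors
are flagged `low_content`: complex ratios (branch density, per-neuron
averages) computed from a handful of small fragments are unreliable, and the
condition summaries exclude flagged values while reporting how many were
excluded. The Z-factor uses the standard
`1 − 3(σ₊ + σ₋)/|μ₊ − μ₋|` definition; coinciding means yield a flagged
`-Inf`, not an exception.

Where the branch count is concerned, the package follows the tips-minus-
attachments direction (clamped at zero): a tree with `A` attachment points
and `E` tips has `E − A` junctions, and the clamp guards the fragmented
regime where attachments can outnumber tips.

## The synthetic generator: what it emulates, what it does not

`generate_field()` renders bright somata (hard disks, radius 9–14 px,
intensity 200/255) and 1-px neurite polylines (intensity 150) on background
20, followed by Gaussian blur (σ = 1 px) and additive Gaussian noise
(SD 4) — sizes and contrasts a 10× objective with a decent neuronal marker
would give. Neurite paths are axis-aligned staircases on the integer grid, a
deliberate choice: the pixel count of an axis-aligned path equals its arc
length, so the generator's "true length" is directly comparable to the
pipeline's pixel-count length without a diagonal correction factor. In
`clean` mode an occupancy map keeps every structure ≥ 5 px from every other
and neurites leave their soma in distinct cardinal directions, which makes
tip/attachment/junction counts exactly recoverable — that is the point:
any count error on clean fields is a pipeline bug, not rendering ambiguity.
`overlap` mode adds unattached soma-crossing neurites (and closer soma
packing) to reproduce the documented failure directions, and `debris` mode
sprinkles sub-threshold specks that a correct size filter must ignore.
`generate_plate()` writes whole plates under the
`{plate}_{well}_f{field}_{channel}.tif` convention with a tab-delimited
truth manifest and annotation table.

What passing tests on these images *does not* show: robustness to uneven
illumination, fasciculated bundles, out-of-focus fields, real PSFs, or
curved neurites whose pixel-count length genuinely underestimates arc
length. Those belong to validation on real data; the synthetic suite
validates the algorithmic contract.

For calibrated screens the generator exposes `max_turns = 0` (straight
radial neurites of exactly the requested length), `placement_margin` and
`min_soma_gap` (so no structure can be truncated or collide), and
`length_scale_sd` (per-field Gaussian variation of the length scale). The
acceptance screen uses condition scales N(1, 0.05) vs N(0.4, 0.05) over a
deterministic base arbor: the closed-form Z-factor of those generating
parameters is 1 − 3(0.05 + 0.05)/(1 − 0.4) = 0.5 independent of the base
length, and the measured Z across 48 fields lands within ±0.15 of it. The
separation controls matter: with turns allowed or somata close enough for
occupancy conflicts, truncated and dropped neurites add geometry-driven
variance that is not part of the designed condition distributions.

## Numerical and design choices

* **Connectivity**: 8-connectivity for foreground (neurites, skeletons,
  somata), 4-connectivity for background hole counting — the standard
  Jordan-compatible pairing.
* **Thresholds** use strict `>`; any consistent convention works, this one
  is fixed and documented.
* **Subtraction clamps at zero** — wrap-around would create spurious bright
  noise in the top-hat.
* **Endpoints by neighbour counting**: on one-pixel-wide skeletons this is
  provably identical to eroding terminal pixels and subtracting, and
  cheaper; the brute-force construction is kept as a test oracle.
* **Component labelling** builds the pixel adjacency edge list and takes
  graph components (igraph); a queue-based flood fill serves as the
  independent oracle in tests.
* **Size filtering precedes thinning** (debris removal before
  skeletonization), and the soma mask is size-filtered as well with its own
  conservative minimum — filtering only the neurite branch is a supported
  deviation knob (`soma_min_area = 0`).
* **Per-well heatmap values** are means over the well's fields; the plate
  mean that anchors grey 128 is computed over annotated, non-failed wells
  only (a plate of empty sentinel wells should not crush the dynamic
  range), falling back to all measured wells when nothing is annotated.
  Missing wells render in a magenta sentinel.
* **mean_intensity** is the full-field mean of the raw image (not masked),
  which is what the heatmap's blue channel displays.
* **Determinism**: `measure_field()` is a pure function; batch outputs carry
  no timestamps, so reruns are byte-identical — asserted down to the HTML.
* **Average individual neurite length** divides total length by attachment
  count (neurite roots) by default; dividing by endpoint count is exposed as
  a config switch since the denominator choice is a convention.
* **Cell body cluster size** is the mean component area (not median).

## Problem sizes used in the validation suite

Unit tests run on 48²–400² images; the ground-truth recovery study uses 50
fields of 512² spanning 1–30 neurons; the screen uses 16 wells × 3 fields at
512²; throughput is reported on a 1024² field (about 2–3 s on one core,
thinning dominates). These sizes exercise every code path at full fidelity
while keeping the suite fast enough to run routinely.

## Known limitations

* Per-field only: no single-cell arbor reconstruction or assignment.
* Fasciculated bundles thin to one skeleton line; individual neurites within
  a bundle are not separable.
* Neurites crossing somata are split (two attachment points); V-shaped
  double attachments are undercounted as none.
* Branch counts are inflated by fragmentation; interpret branch density only
  alongside healthy primary measurements (the low-content flag automates the
  obvious cases).
* Skeleton pixel-count length underestimates the Euclidean length of
  diagonal segments by up to √2; the optional diagonal-corrected column
  mitigates but the canonical measure stays the pixel count.
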