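---
title: "cellmapr: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellmapr: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmapr)
```

This vignette documents the science and the engineering decisions inside
`cellmapr`: the data model, the coordinate mathematics, the time-lapse
model, the clustering procedure, the synthetic-data generator that the
test-suite runs against, and the numerical conventions. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## The standard data model

Upstream segmentation and spot-detection programs disagree about almost
everything: coordinate base, file format, column names, what gets saved.
`cellmapr` funnels them into one set of tibbles:

* **meshframe** — one row per cell per frame: the outline polygon, its
  minimum-area bounding box (length, width, angle, center) and the
  outline rotated onto its length axis with midpoint at (0, 0);
* **spotframe** — detected fluorescent foci in image coordinates;
* **spots_relative** — foci joined to their host cell and expressed in
  cell-internal coordinates;
* **objectframe** — fluorescent-object outlines, with cell-relative
  vertices once a host cell is known;
* **tracks** — per-cell time series (time, length, width, mean
  fluorescence, parent);
* **cell_list** — the original input tables, preserved as read, so no
  upstream information is ever lost by standardization.

One pixel convention holds everywhere and is recorded in every saved
manifest: 0-based indices, pixel centers at integer coordinates, y
increasing downward. Importers with 1-based sources subtract 1 and do
nothing else to coordinates. All geometry stays in pixels; physical
units enter only through optional `pixel_size` metadata at presentation
time, which avoids silent unit mixing when inputs from different
programs are combined.

Datasets persist as plain CSV tables plus a `key: value` manifest with
MD5 checksums. Doubles are written with shortest round-trip precision,
so save/load is the identity on all numeric fields; a missing table or
checksum mismatch raises `CorruptDataset` rather than silently loading
partial data.

## Cell-internal coordinates

The cell's frame of reference is the **minimum-area enclosing
rectangle**, computed by rotating calipers over the convex hull. The
box's longer side is the cell's length axis; its angle θ is reported in
degrees in [−90°, 90°). We chose minimum-area (not minimum-width or
hull-principal-axis) because it is the standard caliper object and
matches rod-shaped cells; for the near-circular cocci the box is close
to degenerate and the angle is reported but carries little meaning.

Two tie situations need care:

* a square box fits at two angles 90° apart — ties go to the angle of
  smallest absolute value, so axis-aligned squares report 0°;
* two *different* boxes of a polygon can tie in area exactly. Breaking
  that tie by angle alone is not stable under rotation of the input
  (the angles move with the polygon), so area ties are broken first by
  the longer box length — a rotation-invariant quantity — and only then
  by angle. This is what makes `(length, width)` reproducible no matter
  how the camera happened to be oriented, and it is enforced by a
  property test over randomly rotated polygons.

Orientation rotates the outline by −θ about the box center and moves
the center to the origin; by construction the x-extent then equals the
length and the y-extent the width, and the shoelace area is preserved to
1e−9 relative. A spot at image position (x, y) maps to `(l, d)` by the
same rigid transform, and to normalized coordinates `l_rel = l / L`,
`d_rel = d / W`. The width-axis sign (`d > 0` toward the rotated +y)
is a bookkeeping convention; no biological polarity is implied, and
kymographs handle the resulting pole ambiguity separately (below).

Spot-to-cell assignment uses the even-odd rule with the boundary counted
as inside, so membrane-localized detections behave deterministically.
When touching cells in a chain both contain a spot, the spot goes to the
cell with the nearest box center and is flagged `ambiguous` rather than
discarded — chain segmentation is a known trouble spot and the flags
keep the choice auditable. Spots inside no cell stay in the dataset as
unassigned; assignment never loses or invents spots, and the test-suite
checks this conservation together with agreement against an independent
crossing-number point-in-polygon oracle.

## Importers and dialect honesty

Only two formats get bespoke structured parsers: Oufti-style MAT v5
cell lists (paired left/right contours, N×4 per cell, converted to a
single simple polygon with 2N−2 vertices) and iSBatch-style spot tables
(trajectory ids preserved for track plots). MAT reading and writing is
done by a small Level-5 codec inside the package (uncompressed,
little-endian, double/char/cell/struct arrays — exactly what the dialect
needs). MicrobeJ, SuperSegger, Morphometrics and ObjectJ are supported
through column-mapping presets applied to their delimited exports; their
binary session formats are undocumented and out of scope. Every dialect
the package can read has a fixture writer, closing the
`import(write(X)) = X` round-trip property that the acceptance suite
exercises on randomized datasets.

Cells whose polygon fails the simple-polygon check are skipped and
counted, never repaired: silent geometry repair would bias downstream
size statistics, and segmentation differences between programs and users
are already a major source of variance.

## Time-lapse model

Division detection uses cell length as the proxy: a division is called
between consecutive observations when the length drops by more than a
fraction δ, with δ = 0.25 by default. A true division halves the length
(−50%), while per-frame growth at realistic rates is ~+2% and
multiplicative observation noise a few percent, so 25% sits far from
both distributions; on the simulator's study conditions (3% length
noise) detection is exact. Explicit genealogy from the segmentation
software, when present, overrides length-based calls.

Percentage-of-division interpolates linearly in *wall-clock time*, not
frame index — movies are often taken at mixed cadences (20 s and 2 min
are both common) and uneven intervals must not distort cycle progress.
The track's first frame counts as a birth only if declared
(`birth_at_start`), because real movies usually start mid-cycle; frames
outside complete cycles are marked incomplete and excluded from
percentage statistics while remaining in the dataset.

Track filtering discards, in order: tracks whose first complete cycle
grows less than a ratio g (default 1.2 — half the doubling a full cycle
implies, tolerant of noise but excluding static artifacts), tracks below
a mean-fluorescence floor, and tracks that never complete a cycle. Each
discard carries a recorded reason, and the discarded fraction is
reported.

Binning by percentage uses [0,10), [10,20), …, [90,100] so that exactly
100% lands in the last bin; aggregates are checked against a brute-force
group-by oracle. Lineage forests (≤ 2 daughters per node, cycle-checked)
export to Newick with branch lengths in seconds; the export is validated
in tests by re-parsing with `ape`.

## Profiles, kymographs and clustering

Length-axis profiles average pixel intensities in 25 equal bins of
`l_rel ∈ [−0.5, 0.5]`; empty interior bins are linearly interpolated
from populated neighbors and flagged. Because the bounding-box frame
assigns no pole identity, consecutive kymograph rows could flip
arbitrarily; each new row is used as-is or reversed, whichever is closer
in L2 distance to the previous row. This keeps a moving band continuous
and is verified against a planted mid-cell-to-quarter sweep.

For clustering, each cell's mean fluorescence versus
percentage-of-division is interpolated onto a 0–100 grid (101 points;
values outside the observed range are nearest-value extrapolated and
flagged). The dissimilarity is Euclidean distance between raw profile
rows by default, with 1 − Pearson r as an option, and clustering is
agglomerative (average linkage by default; complete and Ward.D2
available) cut at k clusters, relabeled by decreasing size.

A design note on normalization: z-scoring each profile row before
Euclidean distance looks natural but is actively harmful for this data.
Cells whose profile is nearly flat — a real and biologically meaningful
behavior — have row variance dominated by noise, and z-scoring inflates
them into unit-variance noise vectors with no mutual similarity. On
planted two-archetype data this collapses recovery (adjusted Rand index
~0.15); on raw rows the same pipeline recovers the planted labels
essentially perfectly (the acceptance suite requires ARI ≥ 0.9 on three
archetypes at 10% noise and measures 1.0). Row z-normalization is
therefore available (`z_normalize = TRUE`) but not the default.

## The synthetic-data generator

The generator defines the conditions under which the analytics are
verified, and its defaults are fixed once:

* **Shapes** — rods (rectangle with semicircular caps), cocci (circles)
  and ovococci (ellipses), discretized so the planted
  (length, width, angle) is recovered by the bounding-box fit to within
  1% discretization error.
* **Growth** — exponential, 0.01/min (doubling ~69 min), division at
  4 px true length into equal daughters, birth lengths uniform within
  ±10% of half the division length, 2-min frame interval, 80 frames per
  track (~2 cycles), 3% multiplicative length observation noise, 10%
  planted non-growers.
* **Fluorescence** — one of three piecewise-linear archetype curves of
  cycle progress (dip-then-recover, gradual, late-drop; fractions
  0.4/0.4/0.2) plus Gaussian noise of sd 0.05, about 10% of the ~0.5
  separation between the curves in their late-cycle region.
* **Images** — background plus isotropic Gaussian spots, optional
  Poisson shot noise; deterministic per seed (R's Mersenne-Twister via
  `set.seed`).

What it deliberately does *not* emulate: optical realism (no Airy
pattern, no camera gain or read noise), segmentation error (meshes are
exact), cell crowding and overlap, asymmetric division, photobleaching,
and the curved medial axis of real bent cells. Passing tests therefore
demonstrate that the coordinate mathematics, bookkeeping and statistical
procedures are correct — not that any particular biological conclusion
transfers to real data, where segmentation quality dominates.

## Numerical choices and degenerate inputs

* Bounding-box area comparisons use 1e−9 relative tolerance; the
  angle-scan oracle used in verification refines a 0.01° exhaustive grid
  with two local passes down to 1e−8°, because area near a caliper
  optimum varies linearly in the angle and a bare 0.01° grid resolves
  area only to ~1e−4 relative.
* Point-on-boundary tolerance is 1e−9 px.
* Polygons must be simple with positive area and at least 3 vertices;
  collinear inputs raise `DegenerateGeometry`; cells covering no pixel
  center raise `EmptyCell`; zero-length/width fits refuse relativization.
* Equal-count length groups sort by (length, cell_id) — the id tiebreak
  makes grouping deterministic under ties — and spread any remainder one
  cell each to the shortest groups.
* Verification problem sizes: 1000 random polygons for the bounding-box
  oracle suite, 10^5 point/polygon pairs, 10^4 relativization
  round-trips, 500 simulated tracks for division recovery, 150 cells for
  cluster recovery. These sizes give the property checks comfortable
  statistical power while keeping the default suite fast.

## Known limitations

Length-axis coordinates come from the bounding-box frame; strongly bent
cells would need a medial-axis ("banana") coordinate system, which is
out of scope. Multi-channel spot frames are kept separate per channel
(`channel` is a column, channels are never merged). The Oufti importer
reads the documented struct layout with a configurable variable name;
historical variants of the format differ and may need a preset or a
small adapter. The CLI covers the standard pipeline; bespoke analyses
are expected to use the R functions directly, which all return plain
tibbles/matrices for that purpose.
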