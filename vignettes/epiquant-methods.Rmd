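---
title: "Methods: image quantification of epithelial shape, co-localization, aggregate overlap and cadherin flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image quantification of epithelial shape, co-localization, aggregate overlap and cadherin flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiquant)
```

epiquant quantifies four kinds of measurements made on confocal images of
epithelial monolayers (the motivating tissue is the *Drosophila* follicular
epithelium, but nothing is fly-specific): polygon classes and areas of
junction-stained cells, object-based co-localization of vesicle-scale
puncta, overlap of intracellular protein aggregates with the Golgi inside a
mutant-cell clone, and the apical extent of cadherin signal along lateral
membranes over an incubation time course. This vignette documents the
models and procedures, the parameters that matter, the numerical choices,
what the synthetic generators emulate, and the known limitations.

## Shared image model

Images are single- or multi-page grayscale TIFFs (8/16-bit). All grids are
R matrices indexed `(row, col)`, 1-based, origin top-left; bounding boxes
are inclusive on both ends. Binarization smooths with a Gaussian of
standard deviation `sigma` (pixels) and thresholds either by Otsu's
between-class-variance criterion over 256 levels of the bit-depth range or
by an absolute intensity. The comparison is strict (`>`): pixels exactly at
the threshold are background, which makes thresholding monotone and
unambiguous. A constant image has no Otsu threshold and is an error rather
than a silent empty mask.

Connected components use 4- or 8-connectivity (stated per use: 4 for cell
interiors, so one-pixel boundary lines separate cells; 8 for puncta and
aggregates, matching particle-analysis convention). Labels are renumbered
1..N by first pixel in column-major order, making every labeling
deterministic.

Region properties report pixel and calibrated areas (`area_um2 = area_px ×
pixel_size_um²`), centroid, bounding box, border contact, an estimated
boundary length, and circularity `4πA/P²`. The perimeter uses a weighted
boundary-chain estimate (straight, diagonal and corner boundary pixels
weighted 1, √2 and (1+√2)/2), which tracks the true contour of smooth
shapes closely; because discrete estimates can make near-circular objects
exceed 1, circularity is clamped at 1.0. A rasterized disc of radius 15
scores ≥ 0.85 while a 5:1 bar of equal area scores far lower, which is the
property the circularity gate relies on.

## Cell-shape analysis

The junction channel is binarized into a boundary mask (optional
morphological closing with `gap_closing_radius` seals staining gaps). Cell
interiors are 4-connected components of the complement; components below
`min_cell_area_px` (default 50) are treated as boundary speckle and
discarded. Interior labels are then expanded outward through the boundary
by iterative 8-neighbour propagation until every pixel belongs to a cell.
This expansion serves two purposes:

* **Areas.** A cell's reported `area_px` is its expanded territory —
  interior plus its share of the junction line. With a 2 px junction line,
  interior-only areas of a 20 px-edge hexagon would read ~10% low; the
  territory area is within 2% of the analytic hexagon area, which is the
  package's internal control (`generate_epithelium(jitter = 0)`).
* **Adjacency.** Two cells are neighbours when their territories meet
  across at least `min_contact_px` (default 3) 4-adjacent pixel contacts.
  The contact minimum suppresses spurious corner contacts (e.g. diagonal
  cells of a square grid meet at a point, not an edge, and are not
  neighbours). This rule needs no estimate of the junction-line width and
  recovered 94–98% of planted tessellation degrees on jittered Voronoi
  epithelia in our tests.

For a tessellating monolayer, a cell's vertices (corners where ≥3 cells
meet) are in bijection with its neighbouring cells, so the vertex count is
the adjacency degree. Filters mirror the published procedure: cells whose
territory reaches the image border are excluded (their shape is clipped),
as are cells with more than 8 vertices; cells with fewer than 4 vertices
(not part of the reported classes) are excluded and tallied. Edge
neighbours still count toward an interior cell's degree — removing them
first would systematically undercount cells adjacent to the border.
Percentages are integers rounded half up (matching how such tables are
printed); the summary reports both `n` (vertex-classified cells) and
`n_area` (cells entering area statistics) because published tables can
differ in the two.

## Object-based co-localization

Detection is the fixed pipeline Gaussian(σ, default 1 px) → threshold
(default Otsu) → binarize → erode (default 1 iteration, cross/diamond
element — the minimal reading of "erode to separate fused vesicles") →
8-connected labeling → area gate (`min_area_px` 5, `max_area_px` 400) →
optional circularity gate (off by default; when on, both bounds must be
given). Gated-out particles are tallied by reason.

Co-localization is strictly object-based (no Pearson/Manders-style
intensity correlation): the two accepted-puncta masks are intersected, and
the result reports both counting conventions — the number of intersection
objects of at least `min_overlap_area_px` pixels (default 1: any shared
pixel), and the number of reference puncta touching the intersection. The
headline fraction is per-reference-punctum, matching the phrasing "x% of
the A puncta overlapped B puncta"; it is asymmetric whenever the two
channels differ in puncta counts, and both directions can be computed by
swapping arguments.

## Aggregate–Golgi overlap

Aggregate and Golgi channels are segmented with channel-tuned Gaussians.
Background reduction, when enabled, subtracts a large-sigma blur before
thresholding (difference of Gaussians); this removes constant offsets and
smooth gradients exactly, which is tested as offset-invariance. It is off
by default; when on, `background_sigma` should be ≥5× the blob sigma.

The clone region is an explicit ROI input — a mask TIFF or a plain-text
polygon (one `row col` vertex per line, closed implicitly, even-odd
filled) — replacing the irreproducible manual deletion of wild-type
objects. Aggregates are kept when their centroid lies inside the ROI
(`"any-pixel"` is available); overlap frequency is defined per-aggregate:
the fraction of kept aggregates sharing ≥1 pixel with the Golgi mask. (How
such a frequency is defined — per aggregate, per area or per cell — is
rarely stated in publications; the per-aggregate definition is labelled in
all outputs.) A scene with no aggregates yields `n = 0` with an
undefined-frequency flag, not an error. Genotype comparisons report the
ratios of overlap frequency, mean aggregate size and count, with an
infinite-ratio flag for a zero denominator.

## Cadherin flow along lateral membranes

Profiles are traced 1D data (CSV columns `cell_id`, `timepoint_min`,
`position_um`, `arm`, `decad`), apical end at position 0 (a `reverse` flag
mirrors basal-to-apical traces); a helper samples a 2D channel along a
polyline at 1 px steps with bilinear interpolation, but automated membrane
tracing is out of scope.

Positivity is relative: a sample is positive when its intensity strictly
exceeds `threshold_fraction` (default 0.2) of the profile's maximum, which
makes the measurement invariant to uniform intensity scaling (and the use
of arc-length positions makes it invariant to unit changes). The total
lateral membrane length runs from the most apical junctional (Arm) positive
sample to the most basal cadherin-positive sample; a non-positive length is
a geometry error naming the cell.

The cadherin extent uses a *front-span* convention: the signal is
interpreted as a front advancing apically from the basal end, so the extent
is the contiguous span anchored at the most basal positive sample. Raw
extremum rules are fragile in noise — one spurious positive sample apical
of the front would redefine the extent — so `measure_extent` (i) smooths
each profile with a centred 5-sample running mean, (ii) ignores positive
runs shorter than 3 samples, and (iii) walks the front apically across gaps
of at most 5 samples, ignoring disconnected apical islands. With these
defaults, planted fronts are recovered within ±3 percentage points down to
signal-to-noise ratio 5; all three mechanisms can be disabled
(`smooth_window = 1`, `min_run = 1`) to obtain the raw threshold rule. A
summed-positive-stretches extent is available via `extent_mode = "summed"`
and reported alongside when wanted.

The kinetics table groups per-cell percentages by incubation timepoint
(design: 1, 3, 5, 8, 12, 19, 25, 30 min) and reports mean, sample s.d. and
n; a single-cell timepoint reports s.d. 0 with `n_cells = 1` as the flag.

## Synthetic scenes and what they do (not) show

Each generator is deterministic given one integer seed; independent scene
components draw from derived sub-streams, so e.g. adding non-reference
puncta does not move the reference placement.

* **Epithelium**: jittered triangular lattice of cell centres,
  nearest-centre tessellation, boundary lines of stated width (default
  2 px) blurred by 0.5 px at intensity 200 over background 10, Gaussian
  noise sd 8. Truth: label image, 4-adjacent tessellation adjacency,
  per-cell areas, the analytic unjittered cell area, and edge labels.
  `jitter = 0` gives a perfect honeycomb (all interior degrees 6);
  `jitter = 0.5` gives a realistic degree distribution with mean ~6.
* **Puncta field**: discs of radius 3–6 px with 1 px anti-aliased rim,
  amplitude 180 over background 15, noise sd 12 (SNR 15), 768 px frame,
  centre separation ≥15 px so distinct puncta never share pixels. A
  planted subset of reference puncta receives an other-channel partner
  offset by at most half the smaller radius (overlap survives one
  erosion); at planted fraction 0 the channels share no mask pixel, so
  recovering exactly 0 is a hard guarantee, not a statistical one.
* **Aggregate scene**: as above with larger discs (radii 4–9 px
  aggregates, 3–6 px Golgi) in a 512 px frame; aggregates sit inside a
  centred rectangular ROI covering 60% of the frame by default.
* **Flow profiles**: junctional channel = apical Gaussian peak (amplitude
  ~1) over a 0.35 plateau; cadherin channel = logistic front of width
  2·L/samples positive basal of `(1 − fraction)·L`, L = 15 µm, 150
  samples, noise sd 0.05, per-cell front jitter sd 0.01 (realized values
  recorded in the truth). The default time-course fractions (0.18 at
  1 min rising to 0.50 at 8 min and 1.00 at 30 min) emulate a front that
  reaches the mid-membrane within 8 min and the apical junction belt by
  30 min.

Passing recovery tests on these scenes demonstrates that the *measurement
machinery* is correct: segmentation, adjacency, gating, intersection
counting and front localization recover what was planted, at the planted
noise levels. It does not validate biological imaging conditions the
generators do not model: out-of-focus light and realistic PSFs, uneven
illumination, autofluorescence, z-stacks, touching vesicles at high
density, curved membranes, or staining artifacts. Published percentages
derived from original micrographs (e.g. specific overlap fractions) can
only be reproduced on those images; here they serve as format and
procedure targets, and the printed count tables are reproduced exactly
from their counts.

## Numerical choices and degenerate inputs

* Thresholds: the original procedures state only that "thresholds were
  applied"; defaults are Otsu with an absolute override, never a guessed
  constant. "Low sigma" defaults to 1 px.
* Rounding: all displayed percentages round half up (`round_half_up`),
  since banker's rounding does not match printed integer tables.
* Ties: threshold ties are background; label-propagation ties during
  territory expansion go to the larger label (moves a territory edge by
  ≤1 px, irrelevant at `min_contact_px` 3); nearest-centre ties in the
  tessellation go to the lower-index centre.
* Degenerate inputs: constant image under Otsu, empty segmentation,
  all-zero profiles, non-positive membrane length, and over-packed
  synthetic scenes raise classed errors; zero aggregates and single-cell
  timepoints return flagged values instead of failing.
* Problem sizes used in the validation suite (chosen to exercise the
  stated conditions at desk scale): honeycombs of ~120 cells at 360 px
  (hexagon edge > 20 px), jittered epithelia of ~280 cells at 448 px
  (≥200 interior cells, 5 seeds), puncta fields of 500+500 at 768 px
  (10 seeds × 5 fractions), aggregate scenes of 100+120 at 512 px
  (5 seeds × 9 frequencies), 50 profiles per flow condition (10 seeds).

## Known limitations

* Vertex counts equal neighbour counts; tricellular-junction point
  detection is deliberately not implemented, so rosettes and four-way
  vertices are read through the adjacency graph.
* The watershed family of seeded segmentations is not offered; cells are
  defined by the junction mask complement, so unsealed junction gaps merge
  cells (mitigate with `gap_closing_radius`).
* Co-localization is binary per object; partial-overlap areas are only
  reported in the aggregate module.
* The flow measurement assumes a single basally anchored front per
  profile; genuinely punctate lateral cadherin would be better served by
  `extent_mode = "summed"`.
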