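---
title: "Quantifying 3D HEV networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D HEV networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

High endothelial venules (HEVs) form branched networks whose remodelling —
new segments, new branch points, a shift toward narrow vessels — signals
lymph-node activation.  `hevquant` turns a light-sheet stack of
PNAd-labelled tissue into an attributed vessel graph and the summary
descriptors of that remodelling.  This vignette is the package's account of
how each stage works, which parameters matter, and where the genuinely open
design choices were resolved.

## The measurement model

The object of interest is a network of roughly tubular, bright-on-dark
structures.  The pipeline assumes:

* vessel signal is brighter than background and approximately bimodal after
  optional smoothing;
* vessel radii are resolved, i.e. at least one voxel after rasterisation on
  the acquisition grid;
* the stack is a single pre-stitched volume (multi-view fusion happens
  upstream).

Internally all grids are `(z, y, x)` arrays; physical coordinates in
exported files are `(x, y, z)` micrometres, the convention of Amira-style
SpatialGraph consumers.  Voxel size is always supplied explicitly (function
argument, YAML sidecar, or pipeline configuration) rather than decoded from
TIFF resolution tags, whose dialects vary between acquisition packages;
this keeps every analysis bit-exactly reproducible from its configuration.

## Segmentation

```{r}
vol  <- preprocess(vol, smooth_sigma_um = 2)      # sigma in um per axis
mask <- binarize(vol, method = "otsu")            # threshold recorded
mask <- clean_mask(mask, min_component_voxels = 27, fill_holes = FALSE)
```

Parameters, with defaults:

* `smooth_sigma_um` (0): Gaussian sigma in micrometres, converted per axis
  to voxels, so one setting serves anisotropic stacks.  Zero disables.
* `method` (`"otsu"`): the source imagery required user-guided threshold
  adjustment and no published rule; Otsu on the (smoothed) volume is the
  parameter-free, reproducible default, with `percentile` and `fixed`
  available for that user guidance.  The applied threshold is stored in the
  mask attributes and the pipeline provenance record, so the "manual" step
  stays auditable.
* `min_component_voxels` (27, i.e. a 3×3×3 speck): 26-connected components
  below this are noise that would otherwise surface as spurious discrete
  networks.
* Tissue envelope: with a single PNAd channel the LN volume is the convex
  hull of the cleaned vessel mask — HEVs span the paracortex, so their hull
  tracks the node outline; when an autofluorescence channel exists,
  thresholding it (largest component, cavities filled) is the more direct
  estimate, and both are exposed because the original measurement's basis
  is not recorded.

## Skeletonization

Thinning removes a voxel only while it is a *simple point* for the (26, 6)
connectivity pair — its deletion provably changes neither the number of
26-connected components nor the number of independent cycles.  Deletions
run in sweeps over the six face directions; candidates are voxels whose
face neighbour in the sweep direction is background when the sweep starts,
processed in eight parity subfields (no two candidates of one subfield are
26-adjacent) and, within a subfield, in increasing distance-transform
order.  Three properties follow:

* **topology is exact** (simple points only), which the test suite checks
  through component counts and the Euler relation
  `#nodes − #segments = #components − #cycles` on every graph it builds;
* **free tube ends recede only about one radius** (directional collection
  bounds erosion to one layer per sweep; the parity subfields stop a
  deletion cascade from running along a one-voxel-thick ribbon within a
  sweep);
* **the curve stays medial** (distance ordering removes outer shells
  first).

Thinning operates on the voxel lattice and ignores anisotropy; the
distance ordering is physically weighted, and lengths/widths are measured
in micrometres downstream.  For extreme z-steps the skeleton may be
slightly off-centre axially — a documented limitation.  Because ties are
broken in raster order, the skeleton is deterministic for a given volume
but *not* exactly equivariant under 90° rotations: counts are preserved,
while total length and mean width move by a fraction of a voxel near
junctions (the property suite checks counts exactly and totals to ~2%).

## From skeleton to graph

Skeleton voxels classify by 26-neighbour count: 1 endpoint, 2 segment
interior, ≥3 junction.  Junction voxels that touch (26-adjacency) merge
into a single node at their centroid so one anatomical branch point does
not splinter; interior runs trace into segments; a node-free closed loop
becomes one self-loop anchored at its lexicographically smallest voxel —
a deterministic tie-break.

**Lengths.**  The raw voxel chain of a digitised straight line
overestimates its length: summing voxel-to-voxel steps along a line in a
generic orientation inflates arc length by up to ~8% in 2D and more in 3D
(the staircase carries axis-aligned and diagonal steps whose sum exceeds
the chord).  Since the validation suite demands total network length
within 5% of ground truth, the package measures length on a
moving-average-smoothed copy of the path (window `smooth_window = 5`
voxels, symmetric, shrinking at the ends) extended to the centroids of its
terminal nodes.  Perfectly axis-aligned and perfectly diagonal paths are
fixed points of the smoother, so the textbook cases (an axis path of ten
2 µm steps measuring 20 µm; a 26-diagonal of ten unit steps measuring
10·√3 µm) remain exact, and connecting interior points to node centroids
lets summed segment lengths tile the skeleton without double counting.

**Widths.**  The physically weighted Euclidean distance transform of the
mask gives each path voxel a local radius; segment width is twice its mean
over interior path voxels after discarding `junction_exclude = 2` voxels
nearest each incident junction, where the EDT inflates at the confluence.
The mean (not median) matches a "mean vessel width" reading of
width-coded renderings.  Two small biases are inherent and tolerated by
the stated accuracy (max of one voxel or 10%): the EDT reaches the centre
of the nearest background voxel, overstating the radius by up to half a
voxel, and the EDT dips within about one radius of a free tube end.

**Pruning.**  `prune_spurs(min_spur_um = 10)` iteratively removes terminal
segments (exactly one end of degree 1) shorter than the threshold, then
dissolves the degree-2 nodes this creates (lengths summed, widths
length-weighted).  The default is one histogram bin width: anything below
the smallest reported vessel class is treated as a thinning artifact.  The
operation terminates, is idempotent, and at threshold 0 is the identity.

**Junction merging.**  Where two tubes meet at an acute angle their union
forms a webbed throat; the skeleton occasionally splits the branch point
into two junction nodes a short distance apart, sometimes joined by a
small ring (one spurious cycle).  `merge_close_junctions(scale = 2)`
contracts junction–junction segments (and drops self-loops) shorter than
`scale` times the local calibre — the widest segment meeting either
endpoint, because the throat skeleton itself is thin.  The bound is
geometric, not fitted: at the generator's minimum branch angle of 40° the
web extends at most about two diameters from the confluence, while
legitimate junction separations sit beyond 2.5 diameters (six radii under
moderate taper).  This step goes beyond plain spur pruning; it exists
because ground-truth recovery on branched phantoms is part of the
package's contract.

**Networks.**  Connected components are ranked by descending total
length (ties by smallest node id); rank 1 is the dominant network.  Both
3D density variants are emitted — µm of vessel per mm³ and segments per
mm³ — because published "HEV density" tables do not state which is meant;
column names disambiguate.

## Binned distributions

Lengths and widths are binned into upper-inclusive intervals
`(w(k−1), wk]` of width `bin_width = 10` µm labelled `"1-10"`, `"11-20"`,
…, so a value of exactly 20 µm falls in `"11-20"`, matching the printed
"between 11 and 20 µm" convention; whether the first bin nominally starts
at 0 or 1 µm is unrecorded, and the labels simply follow the printed
pattern.  Values beyond `cap = 100` µm collect in an open-ended `"> 100"`
bin.  Percentages are of total segment count and sum to 100 within
floating-point error whenever any segment exists.

## 2D section metrics and the median split

`measure_section` takes pre-delineated vessel labels (the original
quantification traced vessels manually; automated 2D detection is out of
scope) and computes HEV area as a percentage of LN section area, vessels
per mm², and mean vessel area — all closed-form on the label image, and
verified in the tests against an independent per-pixel loop.
`classify_hev_status` splits samples at the median of their HEV area
fractions: strictly above ⇒ `hi`, at or below ⇒ `lo`.  The tie rule is a
convention chosen here (the source split does not state one) and the
threshold is echoed in the output; the published cutoff value's units
(fraction vs percent of LN area) are likewise unstated, and the package
treats such values as fractions.

## Tumor growth model

`tumor_volume(length, width)` implements
`length × width × min(length, width) × 3.14/6`, keeping the literal 3.14
of the printed formula for reproducibility (`exact_pi = TRUE` switches to
π).  `fit_growth_rate` fits `D(t) = y0·exp(k·t)` by nonlinear least
squares (the convention of Prism's exponential-growth fit), initialised by
the log-linear regression; `nls` runs with `scaleOffset = 1` so that
noise-free series — where the relative-offset convergence test would
divide by a vanishing residual — converge cleanly.  The sign of `k`
classifies regressors (`k < 0`) vs non-regressors.  One notational wrinkle
in the source description is preserved rather than silently corrected: the
growth-rate formula is written with the diameter difference as the
independent variable *X* even though `k` carries days⁻¹; the intended and
implemented regressor is time, and this ambiguity is documented here.

## The phantom generator: what a green test establishes

`generate_phantom` rasterises a network of capsules (spheres swept along
polylines) at `vessel_level = 200` over `background_level = 50`, optionally
blurred by a Gaussian PSF and degraded with additive Gaussian noise
(`noise_sd = 5` emulates the bimodal N(50, 5)/N(200, 5) contrast of a
bleached, cleared specimen).  Capsule union gives an exact inside/outside
test, so the ground truth — graph, polyline arc lengths, radii, analytic
ellipsoid tissue volume — is closed-form.  Identical spec + seed give
bit-identical volumes.

Procedural trees grow from surface roots of an ellipsoidal domain (45% of
the grid extent by default): straight capsule segments whose length scales
with vessel calibre (6–12 radii, which also enforces the benchmark's
junction separation of at least six radii), branch probability 0.35 per
step by default, branch angles 40–80°, radii 4–10 µm tapering by 0.85 per
generation with a 4 µm floor, self-intersections rejected with a
two-voxel clearance so ground-truth counts stay exact.  When every tip
dies before the target segment count is reached, a fresh surface root is
seeded (bounded retries): without this, crowded domains produce far fewer
segments than specified and a "constant-density family" would not have
constant density.

The validation benchmark is 50 seeded phantoms at 128³ isotropic 2 µm
voxels, radii 2–5 voxels, noiseless, thresholded at the midpoint
intensity — the regime in which segment and branch-point counts are
required to match ground truth exactly in at least 95% of phantoms and
total length to 5% (median).  The constant-density family behind the
volume–length linearity check uses 20 phantoms spanning an 8-fold volume
range with two feeding roots each and branching probability 0.7: the
higher rate is an experiment-design choice, made so the branch-count
signal across the family is not swamped by per-phantom binomial noise at
a sample size the budget allows.  The histogram check draws 500 widths
from a fixed two-component normal mixture and compares against the
closed-form mixture probabilities at a frozen seed.

What the generator does **not** emulate — and therefore what a passing
suite does not establish — includes light-sheet stripe artifacts and depth
attenuation, intensity falloff inside thick specimens, non-circular vessel
cross-sections, curved centerlines within a single growth step, touching
or anastomosing vessels (real HEV networks contain loops; the pipeline
preserves them topologically but the tree generator never creates them
except in explicit topologies), and the inter-operator variability of
manual threshold choice.

## Numerical and format choices

* **TIFF**: a minimal baseline codec (multi-page, single-sample grayscale,
  8/16-bit, uncompressed; both byte orders on read) because no TIFF reader
  is available among the package's permitted dependencies; round-trips of
  integer volumes are bit-exact and cross-checked against an independent
  implementation in the tests.
* **SpatialGraph**: ASCII `AmiraMesh 3D ASCII 2.0` with
  `VertexCoordinates`, `EdgeConnectivity`, `NumEdgePoints`,
  `EdgePointCoordinates` and `thickness` blocks — chosen for direct
  loading into Amira-family renderers; the exact dialect of the original
  tooling is not recorded, so this is an interoperability decision.
  Coordinates are written at six decimals, comfortably inside the 10⁻⁴ µm
  round-trip contract.
* **Determinism**: every stochastic step (phantoms, simulated growth
  series) takes a seed; the pipeline itself is deterministic at fixed
  configuration, and provenance records (configuration, chosen threshold,
  package version) accompany every run.
* **Scale equivariance**: lengths and widths are linear in voxel size,
  volumes cubic, length density inverse-square — exactly, because every
  operation applies physical scaling algebraically; the suite checks this
  with a power-of-two scale factor where floating point preserves
  exactness.

## Known limitations

Anisotropy is compensated metrically but not during thinning; rotation
equivariance is approximate near junctions; EDT radii carry a half-voxel
positive bias and dip near free ends; junction webbing at very acute
branch angles can still defeat the two-diameter merge bound; there is no
hierarchical (Strahler-type) ordering, no flow modelling, and no
learned segmentation.  Sections produced by `section_phantom` use a
maximum-intensity projection of the slab, which slightly dilates
cross-sections of oblique vessels relative to a true physical section.
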