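---
title: "Methods: quantifying mitochondrial redistribution and partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mitochondrial redistribution and partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

## Scope and assumptions

`mitoquant` quantifies the distribution and inheritance of mitochondria in
two-channel fluorescence images of mitotic mouse zygotes and two-cell
embryos. All analyses are strictly 2D: quantified inputs are either single
confocal sections or maximum-intensity Z projections (`max_project()`),
which is how such figures are produced in practice. Channels are assumed
co-registered; intensities are treated as arbitrary units on a linear
scale; physical calibration enters only through the pixel size in µm/px,
which must always be supplied (from TIFF resolution tags or configuration —
there is no silent default).

## Image primitives and their conventions

The quantifications are composed from a small set of primitives whose exact
conventions matter for reproducibility:

* **Gaussian smoothing** (`gaussian_smooth`): the user-facing "radius" is
  the kernel standard deviation in pixels (radius 2 → σ = 2), matching the
  parameter semantics of the interactive software whose workflow this
  package mirrors. The kernel is truncated at 3σ, renormalised (constants
  are exactly preserved), and boundaries are handled by edge replication.
  The default radius everywhere is 2 px.
* **Rolling-ball background subtraction** (`rolling_ball_subtract`): the
  background is the grayscale opening (erosion then dilation) of the image
  by a disk of pixels within distance r of the center, and the result is
  image − background clipped at 0. Default radius 5 px. Within one radius
  of the image border the opening cannot see beyond the frame, so a
  monotone background is reconstructed conservatively there; features
  smaller than the disk are preserved exactly in the interior.
* **Histogram thresholding** (`threshold_yen`, `threshold_moments`): both
  operate on a 256-bin equal-width histogram spanning [min, max] of the
  image, regardless of original bit depth, and a constant image is a
  degenerate-input error. The Yen rule maximises the maximum-correlation
  criterion; ties break toward the lowest level. The Moments (Tsai) rule
  preserves the first three gray-level moments: the binarised image's
  moment-preserving background fraction p_d is computed in closed form and
  the selected level is the one whose cumulative histogram is *closest* to
  p_d (ties toward the lowest level). We chose the closest-quantile rule
  over a strict crossing rule because it is symmetric around p_d: on a
  two-valued histogram with equal classes it yields a foreground fraction
  of exactly one half, which is the behaviour the moment-preservation
  principle implies. Foreground is always *strictly greater than* the
  threshold.
* **Morphology and labeling**: disk structuring elements use the standard
  "distance ≤ r" discretization (a width-1 disk is the 5-pixel cross).
  Particles are connected components under 8-connectivity. The area filter
  is strict (`area > min_area_um2`), with the default cutoff 0.15 µm² below
  which signals are not counted as mitochondrial clusters.
* **Ellipse moments** (`region_ellipse_axes`): axes are those of the
  ellipse with the same second central moments as the pixel set (full axis
  length = 4·√eigenvalue), the convention of standard particle-analysis
  "fit ellipse" output. Collinear regions have minor axis 0 and aspect
  ratio `Inf`.
* **Coordinates** are 0-based, x = column, y = row.

## The named statistics

* **Accumulation ratio**: ring = dilation of the organizer mask by the ring
  width (default 10 px) minus the organizer itself; outside = cell mask
  minus the dilated mask. The statistic is the ratio of *mean per-pixel*
  intensities (not totals), so it does not depend on region sizes; the
  ring and outside regions are disjoint by construction and the organizer
  interior is excluded from both. Empty ring or outside regions are
  degenerate-geometry errors.
* **Partition measures**: the symmetry index (greater/smaller) and
  inheritance ratio (smaller/greater) are computed together, are invariant
  to argument order, and are exact reciprocals. A single zero total yields
  `Inf`/0 with a warning rather than an error, so fully asymmetric
  simulated divisions remain representable.
* **Cleavage-plane split**: pixels are assigned by the signed side of the
  user-supplied line; pixels exactly on the line go to the positive side
  (documented, deterministic). The line must intersect the cell's bounding
  box.
* **Angular non-uniformity**: the center is the spindle-mask centroid and
  the reference axis its equal-moment major axis; sector boundaries start
  at the axis and proceed counterclockwise through six 60° sectors
  (configurable). The channel is smoothed (radius 2 px) first. Because the
  long axis carries a 180° ambiguity, sector *order* is only defined up to
  that ambiguity; the primary statistic is therefore the order-free
  standard deviation of the sector means. An isotropic spindle mask has no
  axis: the angle falls back to 0 rad and the result is flagged. Note that
  on a square pixel grid a discretized circularly symmetric pattern is not
  exactly 60°-sector symmetric, so the statistic has a small discretization
  floor (sub-percent relative); it is exactly zero for constant channels.
* **ROS enrichment**: the inside-mitochondria mask comes from rolling-ball
  subtraction (5 px), smoothing (2 px) and Moments thresholding of the
  mitochondrial channel; the embryo area, when no ROI is supplied, is the
  filled convex hull of the Moments-thresholded smoothed channel
  (`embryo_mask`). The statistic is the ratio of mean ROS intensity inside
  versus outside mitochondria within the embryo.
* **Pixel correlation** is Pearson's r on per-pixel intensities within a
  mask (≥ 10 px, both channels non-constant). Pearson was chosen as the
  default coefficient for co-localization-style comparisons of two
  continuous channels; Manders/overlap coefficients are out of scope.
* **Track projection**: displacements are projected on the unit vector
  from the track's initial to final position, so intermediate motion
  orthogonal to the net displacement contributes zero; the final distance
  to the cell center is reported in µm.

Default parameters are collected in `analysis_config()`: Gaussian radius
2 px, ring width 10 px, rolling-ball radius 5 px, minimum cluster area
0.15 µm², six 60° sectors. Every automatically chosen threshold and region
size is logged (`options(mitoquant.verbose = TRUE)`) so each quantification
can be audited.

## The partition model

The inheritance mechanism is modeled minimally: each cluster is assigned
independently to daughter A with probability p (default 0.5, a
geometrically symmetric division). The model deliberately contains no
spatial structure — division-plane geometry enters only through p — because
the mechanism it formalizes is verbal ("fragmented, dispersed mitochondria
partition stochastically and roughly equally") and any spatial refinement
would be unconstrained guesswork. For n equal clusters the side-A count is
Binomial(n, p), and `exact_partition_distribution()` enumerates every split
with its exact probability (kept to n ≤ 20, the enumeration regime it
certifies); the Monte-Carlo simulator is validated against it in the test
suite. Mass is conserved exactly per replicate, the mean inheritance ratio
is invariant to relabeling the daughters and to p ↔ 1−p, and identical
seeds reproduce identical samples. Measured cluster areas from
`cluster_stats()` can be fed directly to `simulate_partition()`, linking
the image pipeline to the model.

## The synthetic scene generator

`generate_zygote_scene()` emulates the statistical structure the
quantifications assume, with every generative parameter recorded as ground
truth:

* **Puncta** are diffraction-limited-style isotropic Gaussian spots with
  σ = punctum_radius/2, not hard disks. A consequence worth knowing: the
  *thresholded* area of a Gaussian spot depends on the selected level
  (area above level ℓ is 2πσ²·log(peak/ℓ)), so recovered mean cluster
  areas agree with the nominal π·r² only up to a level-dependent factor,
  while cluster *counts* are exact. Tests therefore assert counts tightly
  and areas within a factor of two.
* **Dispersed scenes** use a hard-core point process (default minimum
  separation 2.5 punctum radii): distinct mitochondrial clusters that are
  resolvable in the image are by definition non-coincident, and without the
  hard core a Poisson pattern at realistic densities merges a handful of
  spot pairs under thresholding. Where the planted quantity is an intensity
  *density* (perinuclear enrichment, angular concentration) rather than a
  count, the hard core is disabled (`min_separation_um = 0`) so densities
  stay unbiased.
* **Aggregated scenes** place clumps with Gaussian offsets truncated at
  1.5 spreads around centers kept 6 spreads apart, so each clump renders as
  one contiguous aggregate and clumps never fuse — the generator's contract
  is that `n_clumps` is the true cluster count of the scene.
* **Perinuclear enrichment** multiplies punctum density by f inside a shell
  of configurable width around the organizer; **angular concentration**
  weights punctum angles about the organizer long axis by a von Mises
  density with concentration κ. Both are implemented by rejection sampling
  of the mixture.
* **Two-cell scenes** split the noise-free mitochondrial mass across a
  vertical cleavage line at exactly the requested fraction: whole puncta
  are assigned per side and one fractional-amplitude punctum per side
  absorbs the remainder; puncta keep a 5σ margin from the line so spot
  tails do not leak across.
* **Noise** is applied last: Poisson photon noise at a configurable gain,
  Gaussian read noise, a constant offset and an optional linear background
  gradient. `noise = NULL` renders noise-free, which is what the
  planted-truth tests use.
* **Reproducibility**: all randomness flows from one seed, split into
  documented sub-seeds (positions, mito-channel noise, organizer-channel
  noise), so scenes are bit-identical across runs and channels are
  independently reproducible. A `scene_rotation_rad` parameter rotates the
  realized configuration after sampling, which is how rotation invariance
  of downstream statistics is verified against the *same* scene.

What the generator does **not** emulate: real optics (no PSF model, no
spherical aberration or depth attenuation), 3D structure, time-lapse
dynamics, photobleaching, autofluorescence texture, or cell-to-cell
variability in embryo shape (the embryo is a disk). Passing the recovery
tests therefore demonstrates that the statistics measure what they claim
on data satisfying their assumptions — not that segmentation is robust to
every real-world imaging artifact.

## Problem sizes and numerical tolerances

The test suite and acceptance script run scenes of 384–512 px at
0.1–0.25 µm/px with 120–400 puncta, 6–20 seeds per condition, and
10⁴–10⁵ simulator replicates; these sizes keep every planted-parameter
recovery statistically comfortable. Monte-Carlo agreement with the exact
partition law is asserted within 3 standard errors; planted geometric
quantities (ellipse axes, partition fractions, enrichment factors) are
asserted at 2–10% depending on their sampling noise; identities
(reciprocal partition measures, mirror splits, constant-image smoothing)
are asserted at machine precision or the stated discretization floor.
Threshold selections are asserted to agree *exactly* with exhaustive
criterion search on random histograms.

## Known limitations

* Analyses are 2D only; no 3D segmentation or deconvolution.
* The Moments closest-quantile tie rule can differ by one histogram bin
  from implementations using a strict crossing rule on histograms where
  the cumulative mass jumps across p_d.
* The rolling-ball background is conservative within one radius of the
  image border (see above); quantifications near the frame edge should be
  interpreted accordingly.
* The partition model is non-spatial; whether a division-plane-geometry
  model would fit real zygotes better is untestable from image statistics
  alone and deliberately not guessed at.
* `aspect_ratio` is `Inf` for collinear pixel regions (< 1 px thickness);
  such regions are kept in tables rather than silently dropped.
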