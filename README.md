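# mitoquant

Quantification of mitochondrial redistribution, clustering and partitioning
in fluorescence images of mitotic mouse zygotes, plus a stochastic model of
organelle inheritance.

## The problem

During the first cleavage division of the mouse embryo, mitochondria
redistribute around the pronuclei and the mitotic spindle and must then be
partitioned between the two daughter blastomeres. When mitochondrial fission
is intact, mitochondria are fragmented into many small, dispersed clusters
and inheritance is close to symmetric; when fission is lost, mitochondria
aggregate into a few large clumps, their angular distribution around the
spindle becomes non-uniform, and inheritance becomes biased. `mitoquant`
implements the image statistics used to quantify this phenotype, a
partitioning model that explains it, and a synthetic scene generator so
that every stage can be validated against planted ground truth without any
raw microscopy data.

It is intended for cell and developmental biologists quantifying organelle
distribution and inheritance in single cells or early embryos.

## What it computes

**Image statistics** (all on 2D planes or maximum-intensity projections,
with areas in µm²):

- *Perinuclear/perispindle accumulation ratio*: the organizer (nucleus or
  spindle) mask is dilated by a ring width w (default 10 px); with ring
  R = dilate(M, w) \ M and outside O = cell \ dilate(M, w), the statistic is
  ratio = mean(I[R]) / mean(I[O]).
- *Cluster statistics*: Yen-threshold the mitochondrial channel, label
  8-connected particles, keep those with area > 0.15 µm², report per-cluster
  areas, count, and mean area.
- *Angular non-uniformity*: cytoplasmic pixels are binned into six 60°
  polar sectors anchored at the spindle long axis (from the mask's
  equal-second-moment ellipse); the statistic is the standard deviation of
  the six sector mean intensities.
- *Partition measures*: for totals (a, b) in the two daughters, the
  symmetry index max/min ≥ 1 and the inheritance ratio min/max ∈ (0, 1],
  exact reciprocals.
- *ROS enrichment*: rolling-ball background subtraction (radius 5 px),
  Gaussian smoothing (radius 2 px) and Moments thresholding of the
  mitochondrial channel define the inside-mitochondria mask; the statistic
  is mean ROS intensity inside / outside within the embryo.
- *Morphometry*: major/minor axes and aspect ratio of segmented particles
  from the equal-second-moment ellipse.
- *Pixel correlation* (Pearson, within a mask) and *track projection*
  (displacements projected on the initial-to-final direction; distance to
  cell center).

**Partition model**: each of n clusters with masses s₁…sₙ is assigned
independently to daughter A with probability p (default 0.5). The
inheritance ratio r = min(m_A, m_B)/max(m_A, m_B) concentrates at 1 as n
grows (for equal clusters, m_A is Binomial(n, p)·s), which is why
fragmentation produces symmetric inheritance and aggregation does not.
`exact_partition_distribution()` gives the exact law for n ≤ 20 equal
clusters; `simulate_partition()` is the general Monte-Carlo engine and
accepts measured cluster areas directly.

**Synthetic scenes**: two-channel zygote and two-cell images with planted
punctum positions, clump structure, perinuclear enrichment, angular
concentration, cleavage-plane mass fraction, and Poisson + Gaussian noise;
every planted parameter is recoverable by the corresponding statistic.

## Worked example

```r
library(mitoquant)
p  <- scene_params(seed = 3)           # 512x512 px, 0.25 um/px, 200 puncta
sc <- generate_zygote_scene(p)
cs <- cluster_stats(sc$mito)
cs
#> <cluster stats> 200 clusters, mean area 0.2666 um^2 (Yen threshold 30.2)

# feed measured cluster areas into the partition model
simulate_partition(cs$regions$area_um2, p = 0.5, n_rep = 10000, seed = 3)
#> <partition distribution> 10000 replicates, mean inheritance ratio 0.8945 (sd 0.0746)

# symmetry of inheritance grows with fragmentation
asymmetry_vs_fragmentation(100, c(1, 5, 50, 500), n_rep = 10000, seed = 3)
#>  n_clusters mean_ratio   sd_ratio
#>           1  0.0000000 0.00000000
#>           5  0.4930833 0.23065241
#>          50  0.8106184 0.13146574
#>         500  0.9331575 0.04919643
```

All 200 planted puncta are recovered as clusters; their measured areas,
fed to the simulator, predict a mean inheritance ratio near 0.89 — a
near-symmetric division — whereas the same mass in a handful of clusters
would be strongly biased (0.49 at n = 5).

A command-line wrapper over the same functions is installed at
`inst/cli/mitoquant` (subcommands `clusters`, `accumulation`, `angular`,
`ros`, `partition`, `correlate`, `track`, `simulate`, `synth`; YAML config;
exit codes 0/2/3 for success/parameter error/degenerate input).

## Documentation

`vignettes/mitoquant-methods.Rmd` describes the models and procedures, the
parameter defaults and their provenance, what the synthetic scenes do and
do not emulate, and the package's numerical conventions.
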