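# pavetopo

Topology of pavement-cell tissues: division rules, neighbour statistics and
label-image analysis.

## What this is for

Leaf epidermal pavement cells grow into jigsaw-piece shapes, yet the
*topology* of the tissue — how many neighbours each cell has, summarised by
the distribution P(n) — is set early, before those shapes emerge, and then
barely changes. In a plant tissue cells do not exchange neighbours, so P(n)
is a fossil record of the cell-division history. `pavetopo` is for anyone
who wants to ask, quantitatively, *which division behaviour explains an
observed tissue topology*: modellers simulating topological division rules,
and microscopists with segmented, tracked time-lapse data.

The package provides:

* **A graph-based division simulator.** The tissue is a trivalent planar
  map stored as a rotation system (each cell's neighbours in cyclic
  order). A division of an n-neighboured mother cuts two interfaces — the
  two "junction neighbours" become adjacent to both daughters — and
  splits the remaining n − 2 neighbours into contiguous arcs of sizes a
  and n − 2 − a, so the daughters have a + 3 and n − 2 − a + 3
  neighbours (always summing to n + 4). Three rules set the arc split:
  - *Equal split*: a = (n−2)/2, ties broken uniformly for odd n;
  - *Random split*: a uniform on {0, …, n−2};
  - *Pascal split*: a = 1 + Binomial(n−4, ½) — the Gibson-type binomial
    kernel in which every daughter keeps at least one free neighbour.

  Scheduling is either *without replacement* (every cell divides once per
  round) or *with replacement* (each event picks a uniform random cell).
* **Topology statistics**: P(n) with moments μ1 = ⟨n⟩ and
  μ2 = ⟨n²⟩ − ⟨n⟩²; the Lemaître-type statistic α = μ2·P(6)²;
  analytic and empirical division matrices (per-daughter,
  row-stochastic); Aboav–Weaire curves m_n vs 5 + 8/n; Lewis curves
  Ā_n = (A0/N)(n−2)/4; normalised-area regressions.
* **Label-image topology**: region adjacency by 4-connectivity from
  segmented TIFF/PNG label images, layered boundary-validity tiers,
  areas/centroids/moment-tensor axes, and per-cell heat maps.
* **Lineage tracking**: division-event detection from a four-column
  tracking CSV plus analysed frames, with contamination flagging.
* **Synthetic data**: seeded Voronoi label frames with ground truth,
  two-frame division time-lapses, and i.i.d. rule event streams, so the
  entire pipeline runs and is tested without any microscopy data.

## Worked example

Simulate the equal-split rule without replacement from an 8×8 hexagonal
torus for 10 rounds (65,536 cells) and summarise its steady-state topology:

```r
library(pavetopo)
cfg <- simulation_config("equal", "without", init = c(8, 8), rounds = 10,
                         replicates = 1, seed = 1)
sim <- simulate_tissue(cfg)
sim
#> tissue_sim: equal split, without replacement; 65536 cells pooled
#>   mu1 = 6.0000, mu2 = 1.3235, P(6) = 0.3457
sim$distribution
#> neighbor_distribution over 65536 cells: mu1 = 6.0000, mu2 = 1.3235
#>      4      5      6      7      8      9     10     11     12
#> 0.0708 0.2849 0.3457 0.2009 0.0733 0.0197 0.0039 0.0007 0.0001
alpha_statistic(sim$distribution)
#> [1] 0.1581288
```

The mean is exactly 6 (Euler's relation on the torus); the variance
μ2 ≈ 1.32 and α ≈ 0.158 characterise the broad, five-sided-heavy signature
of the equal-split rule — the signature pavement-cell tissue shares. The
random and pascal rules give μ2 ≈ 10.3 and ≈ 2.7 respectively under the
same protocol.

Every logged division can feed the division-matrix estimator, and the
closed forms are available directly:

```r
analytic_division_matrix("equal", 8)
#> division_matrix (rows: mother n, cols: daughter n, per-daughter probabilities)
#>     3   4   5   6 7 8 9
#> 3 0.5 0.5 0.0 0.0 0 0 0
#> 4 0.0 1.0 0.0 0.0 0 0 0
#> 5 0.0 0.5 0.5 0.0 0 0 0
#> 6 0.0 0.0 1.0 0.0 0 0 0
#> 7 0.0 0.0 0.5 0.5 0 0 0
#> 8 0.0 0.0 0.0 1.0 0 0 0
emp <- empirical_division_matrix(sim$events)   # estimator on the same log
```

For image data, the same statistics flow from a segmented label image:

```r
sf <- voronoi_frame(synthetic_frame_spec(110, c(300, 300), lloyd = 1, seed = 2))
fr <- analyze_frame(sf$frame)            # adjacency, validity tiers, geometry
cells <- fr$cells
distribution_from_counts(cells$n[cells$neighbour_complete])
aboav_curve(fr$adjacency, valid = cells$neighbour_complete)
```

A thin command-line front end (`inst/cli/pavetopo.R`) wires the same
functions into `simulate`, `image-topology`, `divisions`, `synth`, `stats`
and `report` subcommands, each writing CSV/JSON outputs plus a run
manifest.

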