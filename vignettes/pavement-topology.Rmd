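---
title: "Division rules and the topology of pavement-cell tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Division rules and the topology of pavement-cell tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavetopo)
```

## The scientific question

The epidermis of an *Arabidopsis* leaf that carries only pavement cells (the
*speechless* mutant removes the stomatal lineage) is a planar tissue in which
cells essentially never exchange neighbours. Its *topology* — the
distribution P(n) of per-cell neighbour numbers — is therefore a record of
its cell-division history rather than of surface-tension mechanics. The
tissue shows an unusually broad distribution with a low peak at n = 6 and a
characteristic skew towards five-, four- and three-sided cells.

`pavetopo` implements the machinery needed to study this quantitatively:

* a purely topological cell-division simulator on a graph,
* the summary statistics used for cellular mosaics (moments of P(n), the
  Lemaître-type α, Aboav–Weaire and Lewis relations, division matrices),
* an extractor that recovers topology and geometry from segmented label
  images, and a lineage module that turns tracked frames into division
  events,
* synthetic-data generators that replace the original microscopy data, so
  every stage is testable from code alone.

## The graph model

The tissue is an undirected graph: cells are nodes, shared walls are edges.
Because four-way junctions are excluded (they are biophysically avoided and
measure-zero in real tessellations), the map is trivalent and a cell's
neighbour number equals its wall count. A bare graph is not enough to
divide cells: the model needs to know which neighbours are *contiguous*.
Each cell therefore stores its neighbours in cyclic (counter-clockwise)
order — a rotation system, i.e. a combinatorial surface embedding.

A division of a mother with n neighbours:

1. picks a starting wall uniformly among the n interfaces,
2. draws an arc split a (rule-dependent, below),
3. cuts two interfaces; their owners — the *junction neighbours* — become
   adjacent to both daughters,
4. distributes the remaining n − 2 neighbours as contiguous arcs of sizes
   a and n − 2 − a.

The daughters then have a + 3 and (n − 2 − a) + 3 neighbours, so their
total is always n + 4; the two junction neighbours gain one wall each and
nobody else changes, so a division always adds exactly 2 to the
neighbourhood's total neighbour count. These conservation laws are asserted
exhaustively in the test suite (`audit_divisions()` recomputes degrees from
the adjacency itself before and after every division).

The split rules are:

* **Equal split** — a = (n−2)/2 for even n; for odd n the two
  nearest-to-equal splits are taken with probability 1/2 each. The
  unordered daughter pair for odd n is deterministic; only which daughter
  is "first" is random, which has no distributional effect.
* **Random split** — a uniform on {0, …, n−2}: any ratio is equally
  likely.
* **Pascal split** — the binomial kernel of Gibson and colleagues' Markov
  model of proliferating epithelia: every *free* (non-junction) neighbour
  sides independently with either daughter, with each daughter keeping at
  least one, so a = 1 + Binomial(n−4, 1/2) and every daughter has at least
  4 walls. A triangular mother cannot satisfy the minimum and takes the
  only arithmetically possible split, {3, 4}. We use this constrained form
  deliberately: the unconstrained binomial over all n − 2 free neighbours
  (support k ∈ [3, n+1]) over-disperses the steady state (μ2 ≈ 3.8), while
  the constrained kernel reproduces the published steady-state variance of
  the binomial rule (μ2 ≈ 2.7).

Two scheduling schemes are provided. *Without replacement*: every cell
divides exactly once per round, in uniformly shuffled order, asynchronously
(each division sees the updated graph); the population exactly doubles per
round. *With replacement*: each event divides a cell drawn uniformly from
the current population, so lineages drift apart in generation number.

### Initial condition and defaults

The paper-scale protocol starts from an 8×8 hexagonal lattice on a torus
(64 cells) and runs 10 rounds without replacement, giving 65,536 cells per
replicate; replicates are pooled until at least 50,000 cells
(one replicate suffices; the heavy-tailed random rule uses two, ≥100,000
cells). A torus is used because it is boundary-free: Euler's relation for
trivalent maps then pins the mean neighbour number to exactly 6 at all
times, which is also a cheap global invariant for testing. The reference
study reports μ1 = 5.999 rather than 6.000 — a boundary or sampling effect
of its unstated initial tissue that we do not attempt to reproduce.

`make_hex_torus()` rejects lattices so small that wrap-around would make a
cell its own neighbour or list a neighbour twice (below 3×3). The division
bookkeeping assumes simple adjacency; since divisions never create
duplicate adjacencies from a simple start, rejecting degenerate initial
lattices keeps that assumption an invariant rather than a special case.

### Seeding

A simulation is reproducible from a single integer seed; replicate r uses
seed + r. All randomness flows through R's RNG, including inside the C++
core, so `set.seed()` governs everything.

```{r, eval = FALSE}
cfg <- simulation_config("equal", "without", init = c(8, 8), rounds = 10,
                         replicates = 1, seed = 1)
sim <- simulate_tissue(cfg)
sim$distribution       # P(n), mu1, mu2 over 65,536 cells
alpha_statistic(sim$distribution)
```

## Topology statistics

**Moments.** μ1 = ⟨n⟩ and μ2 = ⟨n²⟩ − ⟨n⟩² are computed exactly from the
tabulated counts; μ2 equals the population variance of the raw counts to
machine precision (a test asserts this identity).

**α.** For mosaics peaking at n = 6 the hexagon fraction and the variance
are approximately linked through a single parameter. We implement the
Le Caër–Delannay/Lemaître form α = μ2 · P(6)², the standard concrete
reading of this relation; on the equal-split steady state it evaluates to
≈ 0.156, consistent with the published simulation value, and it is exactly
0 for a perfect honeycomb.

**Division matrices.** Row n gives the probability that a daughter of an
n-neighboured mother has k neighbours. The analytic matrices follow the
closed forms of the three rules; empirical matrices are estimated
per-daughter (each division contributes two observations; rows sum to 1).
Rows with no observed events are reported as undefined (`NA`), never as
zero, and per-row event counts are attached — tracked datasets often
support extreme rows with a single mitotic event. Daughter counts outside
[3, n+1], impossible for an isolated division and symptomatic of a
neighbour dividing within the same tracking interval, are retained but
counted in a `flagged` attribute.

**Aboav–Weaire.** m_n is the mean neighbour count of the neighbours of
n-sided cells, averaged over valid n-sided cells. The default reference
curve is Aboav's original approximate form m_n = 5 + 8/n; the Weaire form
(6 − a) + (6a + μ2)/n with a = 1 is selectable, since the exact printed
form of the reference relation varies across the literature. A test
verifies the exact edge identity Σ P(n)·n·m_n / Σ P(n)·n = edge-weighted
mean degree against direct edge enumeration.

**Lewis.** Ā_n = (A0/N)(n − 2)/4 relates mean area to neighbour number.
When the inputs are locally *normalised* areas (cell area over mean
neighbour area) the A0/N prefactor is replaced by the mean normalised
area, so the reference passes through ≈1 at n = 6; both conventions are
provided because published figures are ambiguous on this point.

**Normalised-area relations.** Per-cell normalised area requires all
neighbours' areas (neighbour-complete validity); the neighbour-mean
normalised area excludes the central cell from each neighbour's own
denominator to avoid the circular "my neighbour is small because I am
large", and therefore requires validity two neighbourhoods deep. Panels
are summarised by ordinary least squares without weighting;
zero-variance relations are flagged degenerate with `NA` statistics rather
than erroring, while fewer than 3 usable cells is an error.

## Label-image topology

`build_adjacency()` uses 4-connectivity: two cells are neighbours iff they
share an edge-adjacent pixel pair. Corner-only contact is deliberately not
adjacency — it would constitute exactly the four-way junction the model
excludes, and 8-connectivity would manufacture such junctions from raster
noise. Segmentations that leave a one-pixel background membrane between
cells are handled by `membrane = 1`, which bridges single background
pixels orthogonally (and then background contact does not disqualify a
cell from being interior).

Validity is layered, mirroring the "fully defined neighbourhood" rule used
for the microscopy data: *interior* (touches neither image border nor
background) ⊃ *neighbour-complete* (all neighbours interior; required for
m_n and normalised areas) ⊃ *second-order-complete* (all neighbours
neighbour-complete; required for the neighbour-mean normalised-area
panel). This is stricter than strictly necessary for some statistics and
documented as such.

Areas are pixel counts times `pixel_size²` — the analyses that matter here
use relative or normalised areas, so absolute calibration is optional.
Axis lengths come from the eigenvalues of the second central moment tensor
of the pixel coordinates with the per-pixel 1/12 term included (each pixel
a unit square), so a w×h rectangle gets exactly the continuous-rectangle
moments and anisotropy (major/minor) of a 20×5 rectangle is exactly 4.
One-pixel regions report anisotropy 1 with a `degenerate` flag.

## Lineage tracking

Tracking is consumed as a plain four-column CSV (`frame_t`, `cell_id_t`,
`frame_t1`, `cell_id_t1`) — any tracker can be adapted to this schema.
One-to-one links are persistence; one-to-two links are candidate
divisions; one-to-many (≥3) and many-to-one links are anomalies, excluded
and reported. An event is *valid* only if the mother is neighbour-complete
at frame t and both daughters at frame t+1. Events whose mother had a
neighbour that also divided in the interval are flagged, not dropped:
such contamination broadens the empirical matrix beyond the de facto
division matrix, and both filtered and unfiltered matrices are
legitimate summaries (`events_to_matrix(drop_contaminated = )`).

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes:

* `voronoi_frame()` — rasterised Voronoi tessellations with known
  adjacency and areas; Lloyd iterations regularise cell shapes (mean
  anisotropy decreases over iterations), and a linear seed-density
  gradient mimics a leaf's tip-to-base cell-size gradient. Ground truth is
  computed by a generator-internal adjacency routine kept separate from
  the extraction code path.
* `divide_frame()` — two-frame time-lapses: selected mothers are split by
  a straight line through the centroid at a uniform random angle, the
  geometric rule that is topologically equivalent to an equal split under
  isotropic conditions. Cuts that would create fragments, undersized
  daughters (below `min_area`, default 12 px) or pixel-level four-way
  junctions are re-drawn (default 25 angle retries, then the mother is
  left undivided) — real tissue and the graph model both exclude four-way
  junctions, so the generator refuses to create them. A stated
  contamination rate forces neighbour co-divisions to exercise the
  flagging logic.
* `rule_event_stream()` — i.i.d. division events drawn from a rule's
  analytic matrix, for estimator tests without any imaging.

The synthetic tissue is deliberately convex — no jigsaw-shaped cells. The
central empirical finding motivating this package is that the topological
signature is established *before* pavement cells acquire their lobed
shapes, so convex tessellations suffice to test every implemented
statistic. Consequently, passing tests certify the pipeline's internal
consistency on convex, well-separated segmentations; they do not certify
equivalence with any specific microscopy segmentation pipeline, nor
behaviour on strongly lobed boundaries.

## Numerical choices and problem sizes

* The simulator core is C++ (via Rcpp); all list bookkeeping is O(degree)
  per division. The paper-scale protocol (65,536 cells per rule) runs in
  well under a second.
* Test problem sizes: steady-state checks pool 65,536–131,072 cells;
  conservation laws are audited over 105,000 divisions; division-matrix
  convergence uses 40,000 samples per mother degree 3–10 per rule
  (320,000 per rule, per-row total variation < 0.01); image-pipeline
  oracles use 110–130-cell frames at ~300² px. These sizes were chosen so
  Monte-Carlo error sits comfortably inside the assertion tolerances.
* Degree-n mothers for matrix sampling are built deterministically:
  forced near-equal splits create degrees below 6, and repeated divisions
  of a target's neighbours (with the target as junction) pump its degree
  above 6.
* Steady-state detection: total-variation distance between consecutive
  pooled round distributions falls below 0.01 by round 8 for the equal
  rule (regression-tested at a fixed seed, pooling five replicate
  tissues to keep sampling noise below the threshold).

## Known limitations

* Simulated graphs are abstract: no geometric embedding, growth, cell
  cycle timing or T1 transitions (neighbour exchanges are rare in plant
  tissue and excluded by design).
* μ1 is exactly 6 on the torus; the 5.999 of boundary-bearing data is not
  reproduced.
* The empirical α of the original microscopy data (≈ 0.150) and its
  806-event empirical division matrix depend on that unavailable dataset;
  the package reproduces the simulation-side quantities and provides the
  estimators for anyone with equivalent tracked segmentations.
* `read_label_image()` supports greyscale integer TIFF/PNG; RGB
  palette-encoded segmentations must be flattened to integer labels
  upstream.
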