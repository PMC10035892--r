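---
title: "Quantifying sub-clonal mixing patterns with class mean first passage times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sub-clonal mixing patterns with class mean first passage times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(cmfpt)
```

## The problem

A tumour section stained for a point mutation shows two cell populations: a
mutant sub-clone (red) and the surrounding wild-type tumour (yellow).  The
spatial arrangement of the two classes — one compact blob, many scattered
islands, fingers along the invasion front — carries a memory of how the
sub-clone grew: how strong its replicative advantage was, how early it
arose, and how much dividing cells pushed their neighbours around.  This
package quantifies such two-class mixing patterns with a single family of
statistics, the *class mean first passage times* (CMFPT) of random walkers,
and inverts the map from growth parameters to patterns by simulation-based
nearest-neighbour inference.

## Class mean first passage times

A pattern is a lattice of sites labelled red, yellow or background.  After
binning (below), the coloured bins form a graph: von Neumann neighbours are
connected, and a walker at a node steps to a uniformly random neighbour.
The first passage time from class $\alpha$ to class $\beta$,
$\tau_{\alpha\beta}$, is the mean number of steps a walker starting on an
$\alpha$ node needs before it first arrives at a $\beta$ node, averaged over
walks and then over all $\alpha$ starting nodes.  Two colours give four
numbers: $\tau_{rr}, \tau_{ry}, \tau_{yr}, \tau_{yy}$.  The start node
itself is not counted, so every $\tau \ge 1$; the same convention is applied
to the same-class diagonal entries.

Raw first passage times scale with pattern size and class abundance, so each
is normalised by its value under a null model: the same graph with node
classes reassigned independently at random, red with probability equal to
the pattern's class ratio $\phi = N_r / (N_r + N_y)$.  Each null realisation
holds its labels fixed while walkers run, and `null_reps` realisations are
averaged.  This quenched construction makes the null the exact counterpart
of a pattern whose colours are iid random — such a pattern therefore sits at
$\tilde\tau_{\alpha\beta} = \tau_{\alpha\beta}/\tau^{null}_{\alpha\beta} = 1$
up to sampling noise, which is the anchor of the method's *phase space*
$(\tilde\tau_{ry},\ \tilde\tau_{ry}/\tilde\tau_{yr})$.  Segregated patterns
push $\tilde\tau_{ry}$ far above 1; the vertical coordinate tells which
class forms the larger clusters.

```{r phase-demo, eval = FALSE}
cfg <- walk_config(walks_per_start = 1000, seed = 1, null_reps = 4)
patterns <- list(
  random  = generate_random(54, 54, 0.5, seed = 1),
  cluster = generate_clusters(54, 54, 0.5, cluster_radius = 3, seed = 2),
  column  = generate_column(54, 54, 0.5))
results <- dplyr::bind_rows(lapply(patterns, function(g) {
  glance(normalized_cmfpt(g, cfg))
}), .id = "model")
plot_phase_space(results)
```

### Downsampling and fractional bins

Real stained sections contain far more pixels than walkers can cover at
reasonable cost, so patterns are first reduced to at most `target_bins`
(default 3000) square bins; the bin side $k$ is the smallest integer meeting
the budget, and grids already inside the budget pass through unchanged.
Each bin keeps the exact *fractions* of red, yellow and background sites it
absorbed.  A walker arriving at a mixed bin reads its class stochastically —
red with probability $f_r/(f_r+f_y)$, drawn afresh on every arrival — so a
bin that is half red and half yellow behaves as either colour with equal
probability.  Bins with no coloured mass are excluded from the graph
entirely: walks never traverse background.  Start nodes contribute to the
class-$\alpha$ average with weight $f_\alpha$, so partial bins count
proportionally.  Analyses that accept a raw grid crop it to the coloured
bounding box before binning, spending the bin budget on tissue rather than
background margins.

### Estimation, truncation and the exact oracle

`estimate_cmfpt()` runs `walks_per_start` walks (default 5000) from every
coloured node in compiled code, recording first passages to both classes in
a single pass.  Walks that exceed `max_steps` (default 200 times the node
count) are discarded and counted; more than 1% truncation triggers a
warning, and a class that no walk reaches is an error rather than a biased
number.  All walk randomness flows from R's RNG, so a `walk_config` seed
makes results exactly reproducible.

`exact_cmfpt()` provides an independent check: absorption of a walker at a
node with probability equal to the node's target-class weight defines a
linear hitting-time system $h = 1 + P\,D\,h$ (with $P$ the transition matrix
and $D$ the diagonal of survival probabilities), solved sparsely.  The test
suite keeps the Monte-Carlo estimator within three standard errors of this
oracle on every fixture graph; the two routes share no code beyond the graph
construction.

## The growth simulator

The generative model is an agent-based birth–death process on a square
lattice (2-D by default, 3-D optional), seeded with one wild-type cell at
the centre.  Its parameters:

| parameter | meaning | default |
|---|---|---|
| `s` | mutant replicative advantage; mutant birth rate $(1+s)\,b_{WT}$ | 1 |
| `n_mut` | fraction of the final size at which the mutation is introduced | 0.1 |
| `q` | pushing strength: maximum cells displaced per division (cells) | 5 |
| `psi` | death coupling: a firing cell dies with probability $\psi$ | 0.3 |
| `n_max` | final total population (cells) | 1e4 |
| `b_wt` | wild-type birth rate (sets the time unit only) | 1 |

Cells are selected to fire with probability proportional to their birth
rate (implemented by rejection sampling, so no clock bookkeeping is
needed; the death coin $d_i = b_i\psi$ is drawn inside the event, making
per-event death probability exactly $\psi$ for both genotypes).  A firing
cell either dies — leaving an empty site — or attempts to divide.  Division
searches for the nearest empty lattice site reachable by pushing a chain of
at most `q` occupied cells: a breadth-first search over occupied sites finds
the minimal chain length, straight-line chains take strict priority over
bent ones of the same length, and remaining ties are resolved at random (a
terminal cell uniformly, then uniformly chosen minimal predecessors — a
random minimal chain, though not exactly uniform over all minimal chains,
which would require path counting).  The chain is displaced one step toward
the empty terminus and the freed neighbour receives a daughter of the
divider's genotype.  With `q = 0` a cell must touch an empty site to divide
— boundary-driven growth.  When the population first reaches
`round(n_mut * n_max)`, one uniformly chosen wild-type cell mutates;
descendants inherit the state and never revert.

Runs in which the whole population dies out, or in which either class is
absent at the end (the mutant lineage lost to drift, or the wild-type
overrun), restart with an incremented seed up to `max_restarts` times —
some parameter corners (late, neutral mutants under strong pushing) fail
often, mirroring the combinations for which reference patterns cannot be
generated at all; `build_library()` records such skips rather than failing.
The lattice side is `ceiling(2.5 * n_max^(1/dims))` with the colony centred,
so growth never reaches the boundary (reaching it is an error, not a
wrap-around).  The von Neumann neighbourhood is used for both division
adjacency and pushing.  Event-level counters (firings, deaths, per-genotype
exposures) are returned so the rate law — mutants firing $(1+s)$ times as
often per cell — and the death fraction $\psi$ can be verified directly
from any run's record.

## Comparator statistics

Two simpler spatial statistics are included for comparison.  *Quadrat
Shannon entropy* tiles the grid into $L\times L$ quadrats (default
$L = 10$), computes the mutant frequency $p_i$ among coloured cells of each
quadrat, and averages the binary entropy
$-[p_i\log_2 p_i + (1-p_i)\log_2(1-p_i)]$ (with $0\log 0 = 0$); because the
value depends on where the quadrat grid is anchored, all $L^2$ offsets are
swept and the minimum reported.  Only complete $L\times L$ quadrats are
scored by default: the offset sweep necessarily slices partial tiles off the
edges, and tiles as small as $1\times1$ are pure by construction, which
would drag the minimum below 1 even for a maximally mixed checkerboard;
`include_partial = TRUE` restores the alternative policy.  Quadrats with no
coloured cells are skipped.  *Mean shortest distance* averages
shortest-path lengths between ordered pairs of cells of two classes on the
coloured-cell adjacency graph (same-class means exclude self-pairs) and
normalises by the same iid-relabelling null.  Both statistics operate at a
single spatial scale, which is precisely the limitation the multi-scale
CMFPT avoids.

## Inference

`build_library()` simulates replicate tumours over a parameter grid
(default $s \in \{0, 0.1, 0.2, 0.5, 1, 2, 3\}$,
$n_{mut} \in \{0.001, 0.01, 0.03, 0.05, 0.08, 0.1, 0.5\}$,
$q \in \{0, 5, 10, 20\}$) and stores each pattern's normalised CMFPT
4-vector and $\phi$.  For an observed pattern, `infer()` takes the $n$
(default 100) nearest library rows in the 4-dimensional space of
componentwise natural logarithms (the log base cannot change rankings, and
rescaling both sides leaves neighbours unchanged).  The rows' parameter
values form discrete posterior marginals; the point estimate is the most
abundant $(s, n_{mut}, q)$ triple, with ties broken by smaller mean
distance and then row order so results are deterministic.  The 95% credible
set of each parameter accumulates grid values in decreasing count order
until 95% of the sample is covered — a greedy highest-density construction,
the natural discrete analogue of a credible region (the reference analysis
names credible regions on a grid without fixing a construction; contiguous
intervals would be the alternative).  $\phi$ is deliberately excluded from
the metric: it is the quantity most distorted when a 2-D section samples a
3-D tumour, and the method is meant to stand on the CMFPT alone.

`validate_inference()` re-classifies library rows by leave-one-out
inference and reports per-value recovery probabilities, the standard check
that strong selection and pushing strength are recovered more reliably than
mutation timing.

## What the generator does and does not emulate

The simulator produces the two-class label grids the statistics consume,
under the growth mechanisms above.  It does not model non-cancerous tissue
(no third class), cell migration, phenotypic switching, parallel origins of
the same mutation, or microenvironment mechanics; patterns derived from
real stained sections additionally carry segmentation noise, resolution
variation, curved tissue boundaries and human curation choices that no
fixture here reproduces.  Tests passing on simulated patterns therefore
validate the statistics and the inference machinery, not biological
conclusions about any particular tissue.

## Numerical choices and problem sizes

* Counts controlled by a fraction (`round(phi * width)`, mutation
  introduction size) round half up, keeping behaviour symmetric around 0.5
  and deterministic.
* The centred disc breaks distance ties in row-major order; the cluster
  generator uses fixed-radius discs with overlap allowed, added until
  $\phi$ is reached — the simplest process with a monotone $\phi$ control.
* Walk truncation uses discard-and-count rather than imputation; the
  default cap (200 × nodes) is far above typical hitting times, and
  analyses of patterns with a nearly extinct minority class either succeed
  with a truncation warning or fail loudly.
* The package's own validation experiment runs at reduced scale: the
  parameter corners $s \in \{0, 3\}$, $n_{mut} \in \{0.001, 0.5\}$,
  $q \in \{0, 20\}$ with 20 replicates per corner, `n_max = 1e4` (large
  enough that a late mutation still leaves selection room to act), 600
  bins, 200 walks per start, 3 null realisations and a 20 000-step cap.
  Replicates whose minority class ends below 10 cells are recorded as
  skipped — an effectively extinct sub-clone has no estimable first
  passage times, the in-package analogue of the parameter combinations for
  which reference patterns cannot be generated at all.  Leave-one-out
  inference uses $n = 5$ neighbours, the square-root-of-class-size
  heuristic for 20 replicates per class; a reference-scale $n = 100$ has
  no meaningful analogue when only ~19 same-combination neighbours exist.
  Full-scale libraries (`n_max = 1e5`, ~100 replicates, 3000 bins, 5000
  walks, $n = 100$) use the same code paths through the same arguments.
* 3-D simulations are supported at reduced `n_max` with the same rules;
  `slice_3d()` extracts the orthogonal planar sections that mimic tissue
  sampling.

## Interfaces

Grids travel as plain-text character grids (`write_grid()`) or PNG/TIFF
rasters classified through a configurable `colour_map()` (nearest reference
colour within a tolerance; everything else is background), with
`extract_subregion()` for manually delineated masks.  Libraries are TSV.
Result objects are tibbles or carry `tidy()`/`glance()` methods, and
`autoplot()`/`plot_phase_space()` give the standard figures.  A thin
command-line wrapper (`inst/scripts/cmfpt-cli`) exposes simulate / analyze /
entropy / msd / infer / fixtures for shell pipelines; it only calls the
functions documented here.

## Known limitations

The CMFPT summarises each transition by its mean; higher moments of the
first-passage distribution are not computed.  The null model and the
fractional-bin walker use slightly different class semantics (fixed labels
per realisation versus per-arrival resampling) — both follow the
construction described above, and the difference is invisible for pure
bins.  Inference is strictly grid-based: parameters between grid values
cannot be returned, and credible sets inherit the grid's resolution.
Finally, 2-D simulations compared against sections of 3-D tissue
systematically reinterpret $n_{mut}$ as a local quantity; the 3-D mode
exists precisely to explore that gap, not to close it.
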