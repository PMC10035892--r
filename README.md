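# cmfpt

Random-walk statistics for two-class spatial cell mixing patterns, an
agent-based simulator of sub-clonal tumour growth, and grid-search inference
of the growth parameters behind an observed pattern.

## The problem

Mutation-specific staining of a tumour section yields a two-colour map:
mutant cells (red) embedded in the wild-type tumour population (yellow).
How the two classes are intermixed — one compact clone, scattered islands,
a sharp interface — encodes the sub-clone's history: its replicative
advantage, how early it arose, and how strongly dividing cells pushed their
neighbours.  `cmfpt` is for researchers who have such label grids (from
in-situ hybridisation masks, segmented histology, or simulations) and want
to (a) quantify the mixing pattern with a statistic that works across
spatial scales and pattern sizes, and (b) estimate which growth dynamics
could have produced it.

## The statistic

Patterns are downsampled to at most 3000 bins that retain their fractional
class composition.  Blind random walkers hop between von-Neumann-adjacent
coloured bins; a bin reads as red with probability
f_r / (f_r + f_y) on each arrival.  The *class mean first passage time*
τ<sub>αβ</sub> is the mean number of steps from a class-α start to the
first class-β arrival, averaged over walks and starts.  Each entry is
normalised by its value under a null model — the same graph with classes
reassigned uniformly at random, preserving the class ratio
φ = N_r / (N_r + N_y):

τ̃<sub>αβ</sub> = τ<sub>αβ</sub> / τ<sup>null</sup><sub>αβ</sub>

An iid-random pattern sits at (τ̃_ry, τ̃_ry/τ̃_yr) = (1, 1); segregation
pushes τ̃_ry up, and the ratio distinguishes which class forms the larger
clusters.  An exact absorbing-chain solver (`exact_cmfpt()`) independently
verifies the Monte-Carlo estimates, and quadrat Shannon entropy /
mean-shortest-distance comparators are included.

The simulator grows a wild-type colony from a single cell by
birth–death events on a lattice (mutant birth rate (1+s)·b_WT; death
coupled to birth, d_i = b_i·ψ with ψ = 0.3; bounded cell pushing along
shortest chains of at most q cells; mutation introduced when the population
first reaches round(n_mut·N_max)).  `infer()` matches an observed pattern's
(τ̃_rr, τ̃_ry, τ̃_yr, τ̃_yy) vector against a simulated library by
log-Euclidean nearest neighbours, yielding discrete posteriors, point
estimates and 95% credible sets for (s, n_mut, q).

## Worked example

```r
library(cmfpt)
library(dplyr)

# four artificial patterns at the same class ratio, increasingly segregated
cfg <- walk_config(walks_per_start = 1000, seed = 1, null_reps = 4)
tab <- bind_rows(lapply(list(
    random   = generate_random(54, 54, 0.3, seed = 1),
    clusters = generate_clusters(54, 54, 0.3, cluster_radius = 3, seed = 2),
    centred  = generate_centred(54, 54, 0.3),
    column   = generate_column(54, 54, 0.3)), function(g)
  glance(normalized_cmfpt(g, cfg))), .id = "pattern")
tab[, c("pattern", "tau_ry_tilde", "ratio_ry_yr", "phi")]
#>    pattern tau_ry_tilde ratio_ry_yr   phi
#> 1   random         1.02       1.007 0.310
#> 2 clusters         6.80       0.563 0.302
#> 3  centred        95.79       1.216 0.300
#> 4   column       235.12       0.549 0.296
```

The iid-random pattern sits at (1, 1) — it *is* the null model — while
τ̃_ry grows by two orders of magnitude from small clusters to full
segregation at the same φ.  Quadrat entropy compresses the same four
patterns onto [0, 1] with far less resolution:
`shannon_entropy(generate_random(54, 54, 0.3, seed = 1))` gives 0.878 and
the column pattern gives exactly 0.

```r
# simulate a moderately selected sub-clone and measure its pattern
sim <- simulate_tumour(sim_params(s = 1, n_mut = 0.1, q = 5, n_max = 1e4,
                                  seed = 9))
sim
#> <tumour_sim> s = 1, n_mut = 0.1, q = 5: 7052 WT + 2948 mutant cells
#>   (phi = 0.295), 2 restarts

glance(normalized_cmfpt(downsample(crop_pattern(sim$grid)),
                        walk_config(walks_per_start = 500, seed = 10,
                                    null_reps = 3)))[,
  c("tau_ry_tilde", "ratio_ry_yr", "phi", "n_nodes")]
#>   tau_ry_tilde ratio_ry_yr   phi n_nodes
#> 1         2.17       0.011 0.295    1196
```

The sub-clone's pattern is clearly non-random (τ̃_ry > 2) and the tiny
ratio says the wild-type population forms the dominant clusters — the
mutant clone is compact within it.  `autoplot(sim$grid)` draws the pattern;
`plot_phase_space()` places many measurements on the standard phase plane.

Parameter inference runs against a simulated reference library:

```r
lib <- build_library(default_param_grid(), reps_per_combo = 100,
                     base_seed = 1)          # full grid; hours of compute
post <- infer(lib, normalized_cmfpt(downsample(crop_pattern(sim$grid))),
              n = 100)
glance(post)        # point estimate + 95% credible sets for s, n_mut, q
validate_inference(lib)   # leave-one-out recovery probabilities
```

`make_fixtures(dir)` writes a small deterministic battery (toy patterns, a
mini library) used by the tests and handy for experimentation, and
`inst/scripts/cmfpt-cli` wraps simulate / analyze / entropy / msd / infer /
fixtures for shell use.

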