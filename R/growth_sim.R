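#' Simulation parameters for sub-clonal tumour growth
#'
#' Bundles the parameters of the agent-based lattice model.  A single
#' wild-type cell seeds an expanding population; cells are selected to fire
#' with probability proportional to their birth rate (b_WT for wild-type,
#' (1 + s) b_WT for mutants).  A firing cell dies with probability `psi`
#' (coupling death to birth, d_i = b_i * psi) and otherwise attempts a
#' division, which succeeds if a chain of at most `q` cells can be pushed
#' along a shortest path into a nearby empty lattice site.  When the total
#' population first reaches `round(n_mut * n_max)` cells, one uniformly
#' chosen wild-type cell acquires the mutation; descendants inherit it and
#' never revert.  The run ends when the population reaches `n_max`.
#'
#' @param s Mutant replicative advantage (>= 0); mutant birth rate is
#'   (1 + s) b_WT.
#' @param n_mut Fraction of the final system size at which the mutation is
#'   introduced, in (0, 1); `n_mut * n_max` must be at least 1.
#' @param q Pushing strength: maximum number of cells a dividing cell may
#'   displace (non-negative integer); q = 0 is boundary-driven growth.
#' @param psi Death coupling in \[0, 1\] (default 0.3).
#' @param n_max Final total population size.
#' @param b_wt Wild-type birth rate (sets the unit of time only; default 1).
#' @param dims 2 or 3 lattice dimensions.
#' @param seed Integer seed; restart r uses `seed + r`.
#' @param max_restarts Maximum restarts after extinction before erroring.
#' @return A `sim_params` list.
#' @export
sim_params <- function(s = 1, n_mut = 0.1, q = 5, psi = 0.3, n_max = 1e4,
                       b_wt = 1, dims = 2, seed = 1, max_restarts = 100) {
  stopifnot(s >= 0, psi >= 0, psi <= 1, q >= 0, n_max >= 1, b_wt > 0,
            dims %in% c(2, 3), max_restarts >= 1)
  if (n_mut <= 0 || n_mut >= 1) stop("`n_mut` must lie in (0, 1)")
  if (n_mut * n_max < 1) stop("`n_mut * n_max` must be at least 1")
  structure(list(s = s, n_mut = n_mut, q = as.integer(q), psi = psi,
                 n_max = as.integer(n_max), b_wt = b_wt,
                 dims = as.integer(dims), seed = as.integer(seed),
                 max_restarts = as.integer(max_restarts)),
            class = "sim_params")
}

sim_side <- function(n_max, dims) as.integer(ceiling(2.5 * n_max^(1 / dims)))

#' Birth and death rates implied by the model parameters
#'
#' Mutant cells divide at rate (1 + s) b_WT; death is coupled to birth, so
#' every rate has a death counterpart b * psi.
#'
#' @param params A [sim_params] object.
#' @return A tibble with one row per genotype: `genotype`, `birth_rate`,
#'   `death_rate`.
#' @examples
#' birth_rates(sim_params(s = 3))
#' @export
birth_rates <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  b <- c(wt = params$b_wt, mut = (1 + params$s) * params$b_wt)
  tibble::tibble(genotype = names(b), birth_rate = unname(b),
                 death_rate = unname(b) * params$psi)
}

#' Simulate an expanding tumour with a mutant sub-clone
#'
#' Runs the agent-based growth model (see [sim_params()]) on an auto-sized
#' lattice (side `ceiling(2.5 * n_max^(1/dims))`, seeded at the centre, so
#' the colony never reaches the boundary).  Runs in which the population, the
#' mutant lineage, or the wild-type lineage (after mutation) goes extinct are
#' restarted with an incremented seed, up to `max_restarts` times.
#'
#' @param params A [sim_params] object (or arguments passed on to it via
#'   `...`).
#' @param ... Used to build `params` when it is not supplied.
#' @return A list of class `tumour_sim` with elements `grid` (a [class_grid]:
#'   mutant = red, wild-type = yellow), `record` (a one-row tibble of run
#'   bookkeeping) and `params`.
#' @examples
#' sim <- simulate_tumour(sim_params(s = 0, n_mut = 0.5, q = 0, n_max = 200,
#'                                   seed = 7))
#' sim$record$pop_at_mutation
#' @export
simulate_tumour <- function(params = NULL, ...) {
  if (is.null(params)) params <- sim_params(...)
  stopifnot(inherits(params, "sim_params"))
  side <- sim_side(params$n_max, params$dims)
  sz <- if (params$dims == 3) side else 1L
  n_intro <- as.integer(round_half_up(params$n_max * params$n_mut))
  max_events <- 3 * params$n_max^1.5 + 1e6

  for (r in 0:params$max_restarts) {
    res <- with_seed_if(params$seed + r, {
      sim_tumour_cpp(side, side, sz, params$s, params$psi, n_intro,
                     params$n_max, params$q, max_events)
    })
    if (res$status == 4) stop("colony reached the lattice boundary; increase the lattice")
    if (res$status == 3) stop("simulation stalled before reaching n_max (event guard hit)")
    two_class <- res$status == 0 && res$n_wt > 0 && res$n_mut > 0
    if (two_class) {
      occ <- res$occ
      lab <- integer(length(occ))
      lab[occ == 2L] <- RED
      lab[occ == 1L] <- YELLOW
      dims <- if (params$dims == 3) c(side, side, side) else c(side, side)
      # occ is x-fastest; class_grid rows index y, so transpose the 2-D case
      grid <- if (params$dims == 2) {
        class_grid(t(matrix(lab, nrow = side, ncol = side)))
      } else {
        class_grid(aperm(array(lab, dim = c(side, side, side)), c(2, 1, 3)))
      }
      record <- tibble::tibble(
        s = params$s, n_mut = params$n_mut, q = params$q, psi = params$psi,
        n_max = params$n_max, seed = params$seed,
        pop_at_mutation = res$pop_at_mutation,
        n_wt = res$n_wt, n_mut_cells = res$n_mut,
        phi = res$n_mut / (res$n_wt + res$n_mut),
        firings = res$fires, deaths = res$deaths,
        failed_divisions = res$failed,
        firings_wt = res$fires_wt, firings_mut = res$fires_mut,
        exposure_wt = res$wexpo_wt, exposure_mut = res$wexpo_mut,
        restarts = r
      )
      return(structure(list(grid = grid, record = record, params = params),
                       class = "tumour_sim"))
    }
  }
  stop(sprintf(
    "could not generate a two-class pattern for (s = %g, n_mut = %g, q = %d) within %d restarts",
    params$s, params$n_mut, params$q, params$max_restarts))
}

#' @exportS3Method base::print
print.tumour_sim <- function(x, ...) {
  r <- x$record
  cat(sprintf(
    "<tumour_sim> s = %g, n_mut = %g, q = %d: %d WT + %d mutant cells (phi = %.3f), %d restarts\n",
    r$s, r$n_mut, r$q, r$n_wt, r$n_mut_cells, r$phi, r$restarts))
  invisible(x)
}

#' @rdname simulate_tumour
#' @param x A `tumour_sim`.
#' @export
glance.tumour_sim <- function(x, ...) x$record

# --- low-level division mechanics, exposed for direct use and testing ------

#' Lattice occupancy state for the division mechanics
#'
#' Wraps an occupancy array (0 = empty, 1 = wild-type, 2 = mutant) so the
#' division and push-path primitives can be driven directly.
#'
#' @param occ Integer matrix (2-D, rows = y) or 3-D array.
#' @return A `tumour_state` list with `occ` (x-fastest vector), `sx`, `sy`,
#'   `sz`.
#' @export
tumour_state <- function(occ) {
  if (is.matrix(occ)) occ <- array(occ, dim = c(dim(occ), 1L))
  stopifnot(length(dim(occ)) == 3, all(occ %in% 0:2))
  d <- dim(occ)
  structure(list(occ = as.integer(aperm(occ, c(2, 1, 3))),
                 sx = d[2], sy = d[1], sz = d[3]), class = "tumour_state")
}

state_site <- function(state, x, y, z = 1) {
  (x - 1L) + state$sx * ((y - 1L) + state$sy * (z - 1L))
}

#' Choose a push path for a dividing cell
#'
#' Breadth-first search from the cell over occupied sites to the nearest
#' empty site, with chain length counted in pushed cells (q = 0 admits only
#' an adjacent empty site).  Among minimum-length chains, straight-line
#' chains take strict priority; remaining ties are broken at random.
#'
#' @param state A [tumour_state].
#' @param x,y,z 1-based coordinates of the dividing cell.
#' @param q Maximum chain length.
#' @param seed Optional seed for the random tie-breaks.
#' @return `NULL` if no chain exists, otherwise a list with `chain` (a matrix
#'   of pushed-cell coordinates, possibly 0-row) and `empty_site`
#'   (coordinates of the empty terminus).
#' @export
choose_push_path <- function(state, x, y, z = 1, q = 0, seed = NULL) {
  stopifnot(inherits(state, "tumour_state"))
  cell <- state_site(state, x, y, z)
  if (state$occ[cell + 1L] == 0L) stop("dividing cell site is empty")
  res <- with_seed_if(seed, {
    choose_push_path_cpp(state$occ, state$sx, state$sy, state$sz, cell, as.integer(q))
  })
  if (!res$found) return(NULL)
  unsite <- function(s) {
    x <- s %% state$sx; r <- s %/% state$sx
    cbind(x = x + 1L, y = r %% state$sy + 1L, z = r %/% state$sy + 1L)
  }
  list(chain = unsite(res$chain), empty_site = unsite(res$empty_site)[1, ])
}

#' Attempt a single cell division
#'
#' @inheritParams choose_push_path
#' @return A list with `success`, the updated [tumour_state] (`state`), and
#'   `daughter_site` coordinates (or `NULL` on failure, with the state
#'   unchanged).
#' @export
attempt_division <- function(state, x, y, z = 1, q = 0, seed = NULL) {
  stopifnot(inherits(state, "tumour_state"))
  cell <- state_site(state, x, y, z)
  if (state$occ[cell + 1L] == 0L) stop("dividing cell site is empty")
  res <- with_seed_if(seed, {
    attempt_division_cpp(state$occ, state$sx, state$sy, state$sz, cell, as.integer(q))
  })
  out <- state
  out$occ <- res$occ
  ds <- NULL
  if (res$success) {
    s <- res$daughter_site
    ds <- c(x = s %% state$sx + 1L, y = (s %/% state$sx) %% state$sy + 1L,
            z = s %/% (state$sx * state$sy) + 1L)
  }
  list(success = res$success, state = out, daughter_site = ds)
}

#' Occupancy of a tumour_state as a class_grid-style array
#'
#' @param state A [tumour_state].
#' @return An integer array (rows = y) with the simulator's occupancy codes.
#' @export
state_occupancy <- function(state) {
  aperm(array(state$occ, dim = c(state$sx, state$sy, state$sz)), c(2, 1, 3))
}
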