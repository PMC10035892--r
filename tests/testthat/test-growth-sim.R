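test_that("mutation is introduced exactly when the population reaches round(n_mut * n_max)", {
  sim <- simulate_tumour(sim_params(s = 0, n_mut = 0.5, q = 0, n_max = 200,
                                    seed = 7))
  expect_equal(sim$record$pop_at_mutation, 100L)
  expect_gt(sim$record$phi, 0)
  expect_lt(sim$record$phi, 1)
  expect_equal(sim$record$n_wt + sim$record$n_mut_cells, 200)
})

test_that("disabling death gives zero death events and an exact final size", {
  sim <- simulate_tumour(sim_params(s = 1, n_mut = 0.1, q = 0, n_max = 1000,
                                    psi = 0, seed = 3))
  expect_equal(sim$record$deaths, 0)
  expect_equal(sim$record$n_wt + sim$record$n_mut_cells, 1000)
})

test_that("identical parameters give identical patterns", {
  p <- sim_params(s = 2, n_mut = 0.1, q = 5, n_max = 500, seed = 11)
  expect_identical(unclass(simulate_tumour(p)$grid),
                   unclass(simulate_tumour(p)$grid))
})

test_that("mutant cells fire (1 + s) times as often per cell as wild-type", {
  r <- simulate_tumour(sim_params(s = 2, n_mut = 0.1, q = 5, n_max = 5000,
                                  seed = 13))$record
  ratio <- (r$firings_mut / r$exposure_mut) / (r$firings_wt / r$exposure_wt)
  expect_equal(ratio, 3, tolerance = 0.05)
  rates <- birth_rates(sim_params(s = 2))
  expect_equal(rates$birth_rate[rates$genotype == "mut"] /
                 rates$birth_rate[rates$genotype == "wt"], 3)
})

test_that("sim_params validates its invariants", {
  expect_error(sim_params(n_mut = 0), "n_mut")
  expect_error(sim_params(n_mut = 1e-6, n_max = 1000), "at least 1")
  expect_error(sim_params(psi = 1.5))
  expect_error(sim_params(s = -1))
})

# --- division mechanics ----------------------------------------------------

test_that("q = 0 divisions need an adjacent empty site", {
  st <- tumour_state(matrix(c(1L, 1L, 0L), nrow = 1))
  path <- choose_push_path(st, x = 1, y = 1, q = 0)
  expect_null(path)
  path2 <- choose_push_path(st, x = 2, y = 1, q = 0)
  expect_equal(nrow(path2$chain), 0)
  expect_equal(unname(path2$empty_site[c("x", "y")]), c(3, 1))
  expect_error(choose_push_path(st, x = 3, y = 1, q = 0), "empty")
})

test_that("a unique minimal chain of one cell is found and pushed", {
  st <- tumour_state(matrix(c(1L, 1L, 0L), nrow = 1))
  path <- choose_push_path(st, x = 1, y = 1, q = 1)
  expect_equal(unname(path$chain[1, c("x", "y")]), c(2, 1))
  expect_equal(unname(path$empty_site[c("x", "y")]), c(3, 1))
  res <- attempt_division(st, x = 1, y = 1, q = 1)
  expect_true(res$success)
  occ <- state_occupancy(res$state)
  expect_equal(sum(occ > 0), 3)
  expect_equal(unname(res$daughter_site[c("x", "y")]), c(2, 1))
})

test_that("a full 3x3 block divides with q = 1 but a 5x5 block needs q = 2", {
  occ <- matrix(0L, 5, 5); occ[2:4, 2:4] <- 1L
  res <- attempt_division(tumour_state(occ), x = 3, y = 3, q = 1, seed = 2)
  expect_true(res$success)
  expect_equal(sum(state_occupancy(res$state) > 0), 10)

  occ2 <- matrix(0L, 7, 7); occ2[2:6, 2:6] <- 1L
  st <- tumour_state(occ2)
  fail <- attempt_division(st, x = 4, y = 4, q = 1, seed = 3)
  expect_false(fail$success)
  expect_identical(fail$state$occ, st$occ)  # state unchanged on failure
  expect_true(attempt_division(st, x = 4, y = 4, q = 2, seed = 3)$success)
})

test_that("straight-line chains take strict priority over bent chains", {
  # divider at (x=3, y=3); only straight candidate is rightwards (empty at
  # (5,3)); bent length-1 chains exist via the empty site at (2,2)
  occ <- matrix(1L, 5, 5)
  occ[3, 5] <- 0L  # empty straight-right terminus (y = 3, x = 5)
  occ[2, 2] <- 0L  # empty enabling bent chains (y = 2, x = 2)
  st <- tumour_state(occ)
  for (s in 1:25) {
    path <- choose_push_path(st, x = 3, y = 3, q = 1, seed = s)
    expect_equal(unname(path$chain[1, c("x", "y")]), c(4, 3))
    expect_equal(unname(path$empty_site[c("x", "y")]), c(5, 3))
  }
})

test_that("division pushes the chain one step and preserves genotypes", {
  # row: divider WT, then mutant, then empty; pushing moves the mutant
  st <- tumour_state(matrix(c(1L, 2L, 0L), nrow = 1))
  res <- attempt_division(st, x = 1, y = 1, q = 1)
  occ <- state_occupancy(res$state)
  expect_equal(as.vector(occ[1, , 1]), c(1L, 1L, 2L))
})

test_that("boundary growth without death keeps the colony connected and compact", {
  comp_graph <- function(m, value) {
    idx <- which(m == value)
    node <- matrix(NA_integer_, nrow(m), ncol(m))
    node[idx] <- seq_along(idx)
    h <- nrow(m); w <- ncol(m)
    edges <- NULL
    p <- node[, -w]; q <- node[, -1]; ok <- !is.na(p) & !is.na(q)
    edges <- rbind(edges, cbind(p[ok], q[ok]))
    p <- node[-h, ]; q <- node[-1, ]; ok <- !is.na(p) & !is.na(q)
    edges <- rbind(edges, cbind(p[ok], q[ok]))
    g <- igraph::make_empty_graph(length(idx), directed = FALSE)
    igraph::add_edges(g, t(edges))
  }
  sim <- simulate_tumour(sim_params(s = 1, n_mut = 0.1, q = 0, n_max = 400,
                                    psi = 0, seed = 17))
  m <- grid_layer(crop_pattern(sim$grid))
  # cells are never removed and daughters touch their parent chain, so the
  # occupied set is exactly connected
  occ <- comp_graph((m != 0L) * 1L, 1L)
  expect_equal(igraph::count_components(occ), 1)
  # interior holes are transient (any neighbour can divide into them), so at
  # termination only a handful of empty pockets may remain
  pad <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  emp <- comp_graph((pad == 0L) * 1L, 1L)
  comps <- igraph::components(emp)
  interior_sites <- sum(comps$csize[-which.max(comps$csize)])
  expect_lte(interior_sites, 0.02 * sum(m != 0L))
})

# --- 3-D growth and slicing ------------------------------------------------

test_that("3-D simulations slice into label-preserving planes", {
  sim <- simulate_tumour(sim_params(s = 1, n_mut = 0.2, q = 2, n_max = 300,
                                    dims = 3, seed = 19))
  vol <- crop_pattern(sim$grid)
  d <- dim(vol)
  totals <- sapply(1:2, function(lab) sum(unclass(vol) == lab))
  slice_totals <- rowSums(sapply(seq_len(d[3]), function(z) {
    s <- slice_3d(vol, "z", z)
    sapply(1:2, function(lab) sum(unclass(s) == lab))
  }))
  expect_equal(slice_totals, totals)
  # re-stacking z-slices reproduces the volume
  restack <- array(0L, dim = d)
  for (z in seq_len(d[3])) restack[, , z] <- grid_layer(slice_3d(vol, "z", z))
  expect_identical(restack, array(unclass(vol), dim = d))
  # slicing along x and y conserves class totals too
  x_totals <- rowSums(sapply(seq_len(d[2]), function(i) {
    s <- slice_3d(vol, "x", i)
    sapply(1:2, function(lab) sum(unclass(s) == lab))
  }))
  expect_equal(x_totals, totals)
  expect_error(slice_3d(vol, "z", d[3] + 1), "out of range")
})

test_that("slicing a uniform cube gives a uniform plane", {
  cube <- class_grid(array(1L, dim = c(4, 4, 4)))
  sl <- slice_3d(cube, "y", 2)
  expect_true(all(unclass(sl) == 1L))
  expect_equal(dim(sl)[1:2], c(4L, 4L))
})
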