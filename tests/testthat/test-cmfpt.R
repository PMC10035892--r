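test_that("exact hitting times reproduce hand-solved toy chains", {
  ex <- exact_cmfpt(ryr_grid())
  expect_equal(tau_of(ex, "r", "r"), 2)
  expect_equal(tau_of(ex, "r", "y"), 1)
  expect_equal(tau_of(ex, "y", "r"), 1)
  expect_equal(tau_of(ex, "y", "y"), 2)
  ex2 <- exact_cmfpt(ry_grid())
  expect_equal(tau_of(ex2, "r", "y"), 1)
  expect_equal(tau_of(ex2, "y", "r"), 1)
  expect_equal(tau_of(ex2, "r", "r"), 2)
  expect_equal(tau_of(ex2, "y", "y"), 2)
})

test_that("Monte-Carlo estimates agree with the exact oracle on small graphs", {
  cfg <- function(seed) walk_config(walks_per_start = 3000, seed = seed)
  # pure and fractional fixtures, all well under 100 nodes
  fixtures <- list(
    ryr_grid(),
    ry_grid(),
    generate_random(8, 8, 0.5, seed = 1),
    generate_random(9, 7, 0.2, seed = 2),
    downsample(crop_pattern(random_grid(16, 16, seed = 3)), target_bins = 64),
    downsample(crop_pattern(random_grid(14, 18, seed = 4)), target_bins = 49)
  )
  for (i in seq_along(fixtures)) {
    ex <- exact_cmfpt(fixtures[[i]])
    est <- estimate_cmfpt(fixtures[[i]], cfg(i))
    z <- abs(est$tau - ex$tau) / pmax(est$se, 1e-12)
    expect_lt(max(z), 3)
  }
})

test_that("walks start outside the start node, so tau >= 1 everywhere", {
  est <- estimate_cmfpt(generate_random(10, 10, 0.5, seed = 5),
                        walk_config(walks_per_start = 200, seed = 6))
  expect_true(all(est$tau >= 1))
})

test_that("colour swap exchanges the class-pair roles", {
  # exact algebraic duality, including fractional bins
  b <- downsample(crop_pattern(random_grid(16, 16, seed = 7)), target_bins = 64)
  swapped <- b
  swapped$f_red <- b$f_yellow
  swapped$f_yellow <- b$f_red
  ex <- exact_cmfpt(b)
  exs <- exact_cmfpt(swapped)
  expect_equal(tau_of(ex, "r", "y"), tau_of(exs, "y", "r"))
  expect_equal(tau_of(ex, "r", "r"), tau_of(exs, "y", "y"))
  expect_equal(tau_of(ex, "y", "r"), tau_of(exs, "r", "y"))
  expect_equal(tau_of(ex, "y", "y"), tau_of(exs, "r", "r"))
  # bitwise duality of the estimator on pure patterns (shared RNG stream)
  g <- generate_random(12, 12, 0.4, seed = 8)
  a <- estimate_cmfpt(g, walk_config(walks_per_start = 400, seed = 9))
  s <- estimate_cmfpt(swap_classes(g), walk_config(walks_per_start = 400, seed = 9))
  expect_identical(tau_of(a, "r", "y"), tau_of(s, "y", "r"))
  expect_identical(tau_of(a, "r", "r"), tau_of(s, "y", "y"))
  expect_identical(tau_of(a, "y", "r"), tau_of(s, "r", "y"))
  expect_identical(tau_of(a, "y", "y"), tau_of(s, "r", "r"))
})

test_that("walk graphs exclude background bins and renormalise mixed bins", {
  wg <- walk_graph(downsample(ryr_grid()))
  expect_equal(nrow(wg$nodes), 3)
  expect_equal(wg$indptr, c(0L, 1L, 3L, 4L))  # path graph degrees 1, 2, 1
  # a bin with fractions (0.3, 0.3, 0.4) reads red with probability 0.5
  b <- downsample(ryr_grid())
  b$f_red[2] <- 0.3; b$f_yellow[2] <- 0.3; b$f_empty[2] <- 0.4
  wg2 <- walk_graph(b)
  expect_equal(wg2$nodes$p_red[2], 0.5)
  # background-only bins are dropped from the graph
  g <- class_grid(matrix(c(1L, 2L, 0L, 2L), nrow = 1))
  expect_warning(wg3 <- walk_graph(downsample(g)), "component")
  expect_equal(nrow(wg3$nodes), 3)
})

test_that("estimation requires both classes and flags heavy truncation", {
  all_red <- class_grid(matrix(1L, 4, 4))
  expect_error(estimate_cmfpt(all_red), "both classes|at least one")
  # two coloured islands separated by background: walks from the red-only
  # component can never reach yellow, so every red start truncates
  m <- matrix(0L, 3, 7)
  m[, 1:2] <- 1L
  m[, 6:7] <- 2L
  g <- class_grid(m)
  suppressWarnings(expect_error(
    estimate_cmfpt(g, walk_config(walks_per_start = 50, max_steps = 100,
                                  seed = 10), targets = "ry"),
    "unreachable|no finite"))
  # the exact solver flags the same situation as a singular system
  suppressWarnings(expect_error(exact_cmfpt(g, targets = "ry"), "singular|unreachable"))
})

test_that("a pattern of independently random colours sits near (1, 1)", {
  res <- normalized_cmfpt(generate_random(40, 40, 0.5, seed = 11),
                          walk_config(walks_per_start = 1500, seed = 12,
                                      null_reps = 5))
  g <- glance(res)
  expect_equal(g$tau_ry_tilde, 1, tolerance = 0.08)
  expect_equal(g$ratio_ry_yr, 1, tolerance = 0.08)
})

test_that("the mirror-symmetric column pattern has tau_ry = tau_yr", {
  res <- normalized_cmfpt(generate_column(60, 50, 0.5),
                          walk_config(walks_per_start = 1000, seed = 13,
                                      null_reps = 4))
  g <- glance(res)
  expect_equal(g$tau_ry_tilde / g$tau_yr_tilde, 1, tolerance = 0.1)
  expect_gt(g$tau_ry_tilde, 1)  # segregated pattern: well above the null
})

test_that("stronger segregation raises the normalised red-to-yellow time", {
  cfg <- walk_config(walks_per_start = 800, seed = 14, null_reps = 3)
  col <- glance(normalized_cmfpt(generate_column(54, 54, 0.5), cfg))
  clu <- glance(normalized_cmfpt(
    generate_clusters(54, 54, 0.5, cluster_radius = 3, seed = 15), cfg))
  expect_gt(col$tau_ry_tilde, clu$tau_ry_tilde)
})

test_that("normalisation divides out pattern size (2x2 tiling invariance)", {
  base <- grid_layer(generate_clusters(27, 27, 0.4, cluster_radius = 3, seed = 16))
  tiled <- class_grid(rbind(cbind(base, base), cbind(base, base)))
  cfg <- walk_config(walks_per_start = 1200, seed = 17, null_reps = 4)
  a <- glance(normalized_cmfpt(class_grid(base), cfg))
  b <- glance(normalized_cmfpt(tiled, cfg))
  expect_equal(b$tau_ry_tilde / a$tau_ry_tilde, 1, tolerance = 0.15)
})

test_that("normalized results are deterministic given a seed", {
  cfg <- walk_config(walks_per_start = 200, seed = 18, null_reps = 2)
  g <- generate_random(15, 15, 0.4, seed = 19)
  expect_identical(glance(normalized_cmfpt(g, cfg)),
                   glance(normalized_cmfpt(g, cfg)))
})

test_that("tidy and glance expose the tau table and phase coordinates", {
  res <- normalized_cmfpt(generate_random(12, 12, 0.5, seed = 20),
                          walk_config(walks_per_start = 150, seed = 21,
                                      null_reps = 2))
  td <- tidy(res)
  expect_setequal(paste0(td$from, td$to), c("rr", "ry", "yr", "yy"))
  expect_true(all(td$tilde > 0))
  gl <- glance(res)
  expect_equal(gl$ratio_ry_yr, gl$tau_ry_tilde / gl$tau_yr_tilde)
  expect_equal(gl$phi, class_ratio(generate_random(12, 12, 0.5, seed = 20)))
})
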