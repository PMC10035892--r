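fake_library <- function(n_per = 10, combos = NULL, jitter = 0.02, seed = 1) {
  # deterministic synthetic library: each combo sits at its own location in
  # log-tau space with a small jitter per replicate
  if (is.null(combos)) {
    combos <- tidyr::expand_grid(s = c(0, 3), n_mut = c(0.01, 0.5), q = c(0, 20))
  }
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
      centre <- exp(c(0.2 * i, -0.1 * i, 0.05 * i, 0.15 * i))
      tibble::tibble(
        s = combos$s[i], n_mut = combos$n_mut[i], q = combos$q[i],
        seed = seq_len(n_per),
        tau_rr = centre[1] * exp(rnorm(n_per, 0, jitter)),
        tau_ry = centre[2] * exp(rnorm(n_per, 0, jitter)),
        tau_yr = centre[3] * exp(rnorm(n_per, 0, jitter)),
        tau_yy = centre[4] * exp(rnorm(n_per, 0, jitter)),
        phi = 0.5)
    }))
  })
}

test_that("log-Euclidean distance matches its closed forms", {
  expect_equal(log_euclidean_distance(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  expect_equal(log_euclidean_distance(c(1, 1, 1, 1), c(exp(1), 1, 1, 1)), 1)
  u <- c(0.5, 2, 1.5, 3); v <- c(1.2, 0.7, 2.5, 1)
  expect_equal(log_euclidean_distance(u, v), log_euclidean_distance(v, u))
  expect_error(log_euclidean_distance(c(0, 1, 1, 1), c(1, 1, 1, 1)), "positive")
})

test_that("a degenerate library returns its single combination", {
  lib <- fake_library(n_per = 100, combos = tibble::tibble(s = 2, n_mut = 0.05,
                                                           q = 5))
  post <- infer(lib, c(1, 1, 1, 1), n = 100)
  expect_equal(post$estimate$s, 2)
  expect_equal(post$estimate$n_mut, 0.05)
  expect_equal(post$estimate$q, 5)
  expect_equal(post$credible$s, 2)
  expect_equal(post$credible$n_mut, 0.05)
  expect_equal(post$credible$q, 5)
})

test_that("n = 1 inference returns the combo of the nearest row", {
  lib <- fake_library()
  i <- 17
  post <- infer(lib, unlist(lib[i, c("tau_rr", "tau_ry", "tau_yr", "tau_yy")]),
                n = 1)
  expect_equal(post$estimate$s, lib$s[i])
  expect_equal(post$estimate$n_mut, lib$n_mut[i])
  expect_equal(post$estimate$q, lib$q[i])
  expect_equal(post$sample$distance[1], 0)
})

test_that("posterior bookkeeping: marginals sum to n, credible sets cover the mode", {
  lib <- fake_library(n_per = 25)
  post <- infer(lib, c(1.1, 0.9, 1.2, 1.3), n = 40)
  sums <- tapply(post$marginals$count, post$marginals$parameter, sum)
  expect_true(all(sums == 40))
  expect_true(post$estimate$s %in% post$credible$s)
  expect_true(post$estimate$n_mut %in% post$credible$n_mut)
  expect_true(post$estimate$q %in% post$credible$q)
  expect_equal(sum(post$marginals$prob[post$marginals$parameter == "s"]), 1)
})

test_that("rankings are invariant under componentwise rescaling", {
  lib <- fake_library()
  q <- c(1.3, 0.8, 1.1, 0.9)
  a <- infer(lib, q, n = 10)
  lib2 <- dplyr::mutate(lib, tau_rr = tau_rr * 7, tau_ry = tau_ry * 0.2,
                        tau_yr = tau_yr * 3, tau_yy = tau_yy * 11)
  b <- infer(lib2, q * c(7, 0.2, 3, 11), n = 10)
  expect_equal(a$sample$seed, b$sample$seed)
  expect_equal(a$sample$s, b$sample$s)
  expect_identical(glance(a)[, c("s", "n_mut", "q")],
                   glance(b)[, c("s", "n_mut", "q")])
})

test_that("inference is deterministic and validates its inputs", {
  lib <- fake_library()
  q <- c(1, 1, 1, 1)
  expect_identical(infer(lib, q, n = 20)$sample, infer(lib, q, n = 20)$sample)
  expect_error(infer(lib, q, n = nrow(lib) + 1), "smaller n")
  expect_error(infer(lib, c(-1, 1, 1, 1), n = 5), "positive")
})

test_that("libraries round-trip through TSV", {
  lib <- fake_library(n_per = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_library(lib, path)
  back <- read_library(path)
  expect_equal(as.data.frame(back), as.data.frame(lib), tolerance = 1e-12)
})

test_that("self-validation recovers well-separated synthetic combos", {
  lib <- fake_library(n_per = 10, jitter = 0.01)
  val <- validate_inference(lib, n = 5)
  expect_equal(val$modal_accuracy, 1)
  expect_true(all(val$recovery$p_correct == 1))
  gl <- glance(val)
  expect_equal(gl$n_evaluated, nrow(lib))
})

test_that("build_library assembles reproducible rows for a tiny grid", {
  grid1 <- tibble::tibble(s = 1, n_mut = 0.1, q = 0)
  lib <- build_library(grid1, reps_per_combo = 3, base_seed = 5, n_max = 300,
                       target_bins = 200,
                       config = walk_config(walks_per_start = 100, null_reps = 2))
  expect_equal(nrow(lib), 3)
  expect_true(all(lib$s == 1))
  expect_true(all(lib$tau_ry > 0))
  lib2 <- build_library(grid1, reps_per_combo = 3, base_seed = 5, n_max = 300,
                        target_bins = 200,
                        config = walk_config(walks_per_start = 100, null_reps = 2))
  expect_equal(as.data.frame(lib), as.data.frame(lib2))
})
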