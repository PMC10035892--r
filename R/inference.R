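#' Default simulation parameter grid
#'
#' The full factorial grid of mutant advantage s, mutation timing n_mut and
#' pushing strength q used to build reference pattern libraries:
#' s in \{0, 0.1, 0.2, 0.5, 1, 2, 3\}, n_mut in \{0.001, 0.01, 0.03, 0.05,
#' 0.08, 0.1, 0.5\}, q in \{0, 5, 10, 20\}.
#'
#' @param s,n_mut,q Grid values; defaults reproduce the full grid.
#' @return A tibble with one row per (s, n_mut, q) combination.
#' @export
default_param_grid <- function(s = c(0, 0.1, 0.2, 0.5, 1, 2, 3),
                               n_mut = c(0.001, 0.01, 0.03, 0.05, 0.08, 0.1, 0.5),
                               q = c(0, 5, 10, 20)) {
  tidyr::expand_grid(s = s, n_mut = n_mut, q = q)
}

#' Build a library of simulated-pattern CMFPT vectors
#'
#' For every parameter combination and replicate: simulate a tumour, crop and
#' downsample the resulting pattern, compute its normalised CMFPT vector, and
#' record a library row.  Replicate seeds are derived deterministically from
#' `base_seed`, so identical inputs reproduce the library row for row.
#' Combinations whose replicates repeatedly fail (e.g. sub-clone extinction
#' exhausting the restart budget) are skipped with a message and recorded in
#' the `skipped` attribute.
#'
#' @param param_grid A data frame with columns `s`, `n_mut`, `q` (default
#'   [default_param_grid()]).
#' @param reps_per_combo Replicate simulations per combination (the reference
#'   analysis uses about 100).
#' @param base_seed Integer seed from which per-replicate seeds are derived.
#' @param n_max,psi Simulator settings shared across the grid.
#' @param config A [walk_config] for the CMFPT estimation (its `seed` is
#'   overridden per replicate).
#' @param target_bins Downsampling budget (default 3000).
#' @param max_restarts Per-replicate restart budget.
#' @param min_class_cells Minimum cell count of the minority class for a
#'   simulated pattern to enter the library (default 10).  A sub-clone (or
#'   remnant wild-type population) of fewer cells is effectively extinct:
#'   its first passage times are not estimable and the replicate is recorded
#'   as skipped, mirroring the parameter combinations for which reference
#'   patterns cannot be generated.
#' @return A tibble with columns `s`, `n_mut`, `q`, `seed`, `tau_rr`,
#'   `tau_ry`, `tau_yr`, `tau_yy` (normalised), `phi`.
#' @export
build_library <- function(param_grid = default_param_grid(),
                          reps_per_combo = 100, base_seed = 1,
                          n_max = 1e5, psi = 0.3,
                          config = walk_config(), target_bins = 3000L,
                          max_restarts = 25, min_class_cells = 10) {
  stopifnot(all(c("s", "n_mut", "q") %in% names(param_grid)))
  combos <- dplyr::distinct(tibble::as_tibble(param_grid[, c("s", "n_mut", "q")]))
  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    for (r in seq_len(reps_per_combo)) {
      seed_r <- rep_seed(base_seed, i, r)
      row <- tryCatch({
        sim <- simulate_tumour(sim_params(
          s = cb$s, n_mut = cb$n_mut, q = cb$q, psi = psi, n_max = n_max,
          seed = seed_r, max_restarts = max_restarts))
        if (min(sim$record$n_wt, sim$record$n_mut_cells) < min_class_cells) {
          stop(sprintf("minority class has %d cells (< %d): sub-clone effectively extinct",
                       min(sim$record$n_wt, sim$record$n_mut_cells),
                       min_class_cells))
        }
        cfg <- config
        cfg$seed <- seed_r + 1L
        res <- normalized_cmfpt(downsample(crop_pattern(sim$grid), target_bins),
                                cfg)
        g <- glance(res)
        tibble::tibble(s = cb$s, n_mut = cb$n_mut, q = cb$q, seed = seed_r,
                       tau_rr = g$tau_rr_tilde, tau_ry = g$tau_ry_tilde,
                       tau_yr = g$tau_yr_tilde, tau_yy = g$tau_yy_tilde,
                       phi = g$phi)
      }, error = function(e) {
        message(sprintf("skipping (s = %g, n_mut = %g, q = %g) rep %d: %s",
                        cb$s, cb$n_mut, cb$q, r, conditionMessage(e)))
        skipped[[length(skipped) + 1]] <<- tibble::tibble(
          s = cb$s, n_mut = cb$n_mut, q = cb$q, seed = seed_r,
          reason = conditionMessage(e))
        NULL
      })
      if (!is.null(row)) rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}

# Deterministic per-replicate seed, kept within 32-bit integer range.
# Replicates are spaced far apart because extinction restarts run at
# seed + r: close-packed seeds would let neighbouring replicates converge on
# the same successful restart seed and duplicate rows.
rep_seed <- function(base_seed, combo, rep) {
  as.integer((as.numeric(base_seed) * 7919 + combo * 104729 + rep * 100003) %% 2147483629L)
}

#' Write / read a pattern library as TSV
#'
#' @param library A library tibble from [build_library()].
#' @param path File path.
#' @return `read_library()` returns the library tibble;
#'   `write_library()` returns `path` invisibly.
#' @export
write_library <- function(library, path) {
  write.table(library, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  tibble::as_tibble(read.delim(path, sep = "\t"))
}

#' Log-Euclidean distance between CMFPT vectors
#'
#' Euclidean distance between the componentwise natural logarithms of two
#' positive vectors.  Rankings are invariant under componentwise rescaling of
#' both vectors and under the choice of logarithm base.
#'
#' @param u,v Positive numeric vectors of equal length (typically the four
#'   normalised CMFPT components).
#' @return A non-negative number.
#' @examples
#' log_euclidean_distance(c(1, 1, 1, 1), c(exp(1), 1, 1, 1))  # 1
#' @export
log_euclidean_distance <- function(u, v) {
  if (length(u) != length(v)) stop("`u` and `v` must have equal length")
  if (any(u <= 0) || any(v <= 0)) stop("components must be positive for the log transform")
  sqrt(sum((log(u) - log(v))^2))
}

tau_cols <- c("tau_rr", "tau_ry", "tau_yr", "tau_yy")

query_vector <- function(query) {
  if (inherits(query, "cmfpt_result")) {
    g <- glance(query)
    q <- c(g$tau_rr_tilde, g$tau_ry_tilde, g$tau_yr_tilde, g$tau_yy_tilde)
  } else if (is.data.frame(query)) {
    stopifnot(all(tau_cols %in% names(query)), nrow(query) == 1)
    q <- unlist(query[1, tau_cols], use.names = FALSE)
  } else {
    q <- as.numeric(query)
  }
  if (length(q) != 4 || any(!is.finite(q)) || any(q <= 0)) {
    stop("query must be 4 positive normalised CMFPT components (rr, ry, yr, yy)")
  }
  q
}

#' Infer growth parameters for an observed pattern
#'
#' Finds the `n` library entries nearest to the query in the 4-dimensional
#' log-CMFPT space (log-Euclidean distance; ties broken by row order).  These
#' form the posterior sample: marginal counts over each parameter's grid
#' values, a point estimate equal to the most abundant (s, n_mut, q) triple
#' (ties broken by smallest mean distance, then row order), and per-parameter
#' 95% credible sets built by accumulating grid values in decreasing count
#' order until at least 95% of the sample is covered.
#'
#' @param library A library tibble (columns `s`, `n_mut`, `q`, `tau_rr`,
#'   `tau_ry`, `tau_yr`, `tau_yy`).
#' @param query A `cmfpt_result`, a one-row data frame with the four tau
#'   columns, or a numeric 4-vector (rr, ry, yr, yy order).
#' @param n Posterior sample size (default 100).
#' @param level Credible level (default 0.95).
#' @return A `cmfpt_posterior`: list with `sample` (the n nearest rows plus
#'   `distance`), `marginals` (tibble: parameter, value, count, prob),
#'   `estimate` (one-row tibble), and `credible` (named list of grid-value
#'   vectors).  [tidy()] returns the marginals, [glance()] the point
#'   estimate with credible ranges.
#' @export
infer <- function(library, query, n = 100, level = 0.95) {
  stopifnot(all(c("s", "n_mut", "q") %in% names(library)),
            all(tau_cols %in% names(library)))
  if (nrow(library) < n) {
    stop(sprintf("library has %d rows, fewer than n = %d; use a smaller n",
                 nrow(library), n))
  }
  q <- query_vector(query)
  logq <- log(q)
  logs <- log(as.matrix(library[, tau_cols]))
  if (any(!is.finite(logs))) stop("library tau components must be positive")
  d <- sqrt(rowSums((logs - rep(logq, each = nrow(logs)))^2))
  ord <- order(d)  # stable: ties keep row order
  take <- ord[seq_len(n)]
  sample <- dplyr::mutate(library[take, ], distance = d[take])

  marginals <- dplyr::bind_rows(lapply(c("s", "n_mut", "q"), function(p) {
    dplyr::count(sample, value = .data[[p]], name = "count") |>
      dplyr::mutate(parameter = p, prob = .data$count / n) |>
      dplyr::select("parameter", "value", "count", "prob")
  }))

  combo <- sample |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$s, .data$n_mut, .data$q) |>
    dplyr::summarise(count = dplyr::n(), mean_distance = mean(.data$distance),
                     first_row = min(.data$.row), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$mean_distance,
                   .data$first_row)
  estimate <- combo[1, c("s", "n_mut", "q", "count", "mean_distance")]

  credible <- lapply(setNames(c("s", "n_mut", "q"), c("s", "n_mut", "q")),
                     function(p) {
    m <- marginals[marginals$parameter == p, ]
    m <- m[order(-m$count, m$value), ]
    kk <- which(cumsum(m$count) >= level * n)[1]
    sort(m$value[seq_len(kk)])
  })

  structure(list(sample = sample, marginals = marginals, estimate = estimate,
                 credible = credible, n = n, level = level, query = q),
            class = "cmfpt_posterior")
}

#' @exportS3Method base::print
print.cmfpt_posterior <- function(x, ...) {
  e <- x$estimate
  cat(sprintf(
    "<cmfpt_posterior> n = %d nearest patterns\n  point estimate: s = %g, n_mut = %g, q = %g (%d/%d)\n",
    x$n, e$s, e$n_mut, e$q, e$count, x$n))
  for (p in names(x$credible)) {
    cat(sprintf("  %g%% credible set %s: {%s}\n", 100 * x$level, p,
                paste(x$credible[[p]], collapse = ", ")))
  }
  invisible(x)
}

#' @rdname infer
#' @param x A `cmfpt_posterior`.
#' @param ... Unused.
#' @export
tidy.cmfpt_posterior <- function(x, ...) x$marginals

#' @rdname infer
#' @export
glance.cmfpt_posterior <- function(x, ...) {
  tibble::tibble(
    s = x$estimate$s, n_mut = x$estimate$n_mut, q = x$estimate$q,
    modal_count = x$estimate$count, n = x$n,
    s_credible = paste(x$credible$s, collapse = ","),
    n_mut_credible = paste(x$credible$n_mut, collapse = ","),
    q_credible = paste(x$credible$q, collapse = ",")
  )
}

#' @rdname infer
#' @param object A `cmfpt_posterior`.
#' @export
autoplot.cmfpt_posterior <- function(object, ...) {
  df <- dplyr::mutate(object$marginals, value = factor(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "parameter value", y = "posterior probability") +
    ggplot2::theme_minimal()
}

#' Validate inference by held-out self-classification
#'
#' Predicts (s, n_mut, q) for library replicates by leave-one-out
#' nearest-neighbour inference against the rest of the library, and reports
#' the probability of exact recovery per true parameter value.
#'
#' @param library A library tibble.
#' @param n Posterior sample size used for each held-out prediction.
#' @param holdout Fraction of library rows to evaluate (default all).
#' @param seed Optional seed for the holdout subsample.
#' @return A list of class `cmfpt_validation`: `predictions` (tibble with
#'   true and predicted parameters per evaluated row), `recovery` (tibble:
#'   parameter, value, n, p_correct), and `modal_accuracy` (fraction of rows
#'   whose full (s, n_mut, q) triple was recovered).
#' @export
validate_inference <- function(library, n = 10, holdout = 1, seed = NULL) {
  stopifnot(nrow(library) > n)
  idx <- seq_len(nrow(library))
  if (holdout < 1) {
    idx <- with_seed_if(seed, sort(sample(idx, max(1, round(holdout * length(idx))))))
  }
  preds <- lapply(idx, function(i) {
    post <- infer(library[-i, ], unlist(library[i, tau_cols], use.names = FALSE),
                  n = n)
    tibble::tibble(
      s = library$s[i], n_mut = library$n_mut[i], q = library$q[i],
      s_hat = post$estimate$s, n_mut_hat = post$estimate$n_mut,
      q_hat = post$estimate$q)
  })
  predictions <- dplyr::bind_rows(preds)
  recovery <- dplyr::bind_rows(lapply(c("s", "n_mut", "q"), function(p) {
    predictions |>
      dplyr::group_by(value = .data[[p]]) |>
      dplyr::summarise(n = dplyr::n(),
                       p_correct = mean(.data[[p]] == .data[[paste0(p, "_hat")]]),
                       .groups = "drop") |>
      dplyr::mutate(parameter = p) |>
      dplyr::select("parameter", "value", "n", "p_correct")
  }))
  modal <- mean(predictions$s == predictions$s_hat &
                predictions$n_mut == predictions$n_mut_hat &
                predictions$q == predictions$q_hat)
  structure(list(predictions = predictions, recovery = recovery,
                 modal_accuracy = modal, n = n),
            class = "cmfpt_validation")
}

#' @exportS3Method base::print
print.cmfpt_validation <- function(x, ...) {
  cat(sprintf("<cmfpt_validation> %d held-out rows, modal-combo accuracy %.2f\n",
              nrow(x$predictions), x$modal_accuracy))
  print(x$recovery)
  invisible(x)
}

#' @rdname validate_inference
#' @param x A `cmfpt_validation`.
#' @param ... Unused.
#' @export
tidy.cmfpt_validation <- function(x, ...) x$recovery

#' @rdname validate_inference
#' @export
glance.cmfpt_validation <- function(x, ...) {
  tibble::tibble(modal_accuracy = x$modal_accuracy,
                 n_evaluated = nrow(x$predictions), n_neighbours = x$n)
}
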