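#' Random-walk configuration
#'
#' @param walks_per_start Number of walks launched from every coloured bin
#'   (default 5000).
#' @param max_steps Cap on walk length; walks exceeding it are discarded and
#'   counted as truncated.  Default 200 times the number of walk-graph nodes
#'   (resolved at run time when `NULL`).
#' @param seed Optional integer seed governing all walk randomness (raw and
#'   null campaigns draw from one seeded stream).
#' @param null_reps Number of independent null-model walk campaigns averaged
#'   for the normalisation (default 10).
#' @return A `walk_config` list.
#' @export
walk_config <- function(walks_per_start = 5000, max_steps = NULL, seed = NULL,
                        null_reps = 10) {
  stopifnot(walks_per_start >= 1, is.null(max_steps) || max_steps >= 1,
            null_reps >= 1)
  structure(list(walks_per_start = as.integer(walks_per_start),
                 max_steps = max_steps, seed = seed,
                 null_reps = as.integer(null_reps)),
            class = "walk_config")
}

#' Build the walk graph of a binned pattern
#'
#' Nodes are the bins carrying coloured mass (w = f_red + f_yellow > 0);
#' edges join von-Neumann-adjacent nodes; a walker moves to a uniformly
#' random neighbour each step.  A node's class is stochastic: on each arrival
#' it reads red with probability f_red / (f_red + f_yellow).  Bins with no
#' coloured mass are excluded, so walks never traverse background.
#'
#' @param binned A `binned_pattern` (or a [class_grid], binned with defaults).
#' @return A `walk_graph` list: `nodes` (tibble with bin coordinates, class
#'   fractions, weights and `p_red`), CSR adjacency (`indptr`, `indices`,
#'   0-based), and `n_components` over the coloured bins.
#' @export
walk_graph <- function(binned) {
  binned <- as_binned(binned)
  w <- binned$f_red + binned$f_yellow
  keep <- which(w > 0)
  n <- length(keep)
  if (n < 2) stop("walk graph needs at least 2 coloured bins")
  nby <- nrow(w); nbx <- ncol(w)
  id <- matrix(NA_integer_, nby, nbx)
  id[keep] <- seq_len(n)

  from <- integer(0); to <- integer(0)
  # horizontal and vertical adjacencies between coloured bins
  if (nbx > 1) {
    a <- id[, -nbx]; b <- id[, -1]
    ok <- !is.na(a) & !is.na(b)
    from <- c(from, a[ok], b[ok]); to <- c(to, b[ok], a[ok])
  }
  if (nby > 1) {
    a <- id[-nby, ]; b <- id[-1, ]
    ok <- !is.na(a) & !is.na(b)
    from <- c(from, a[ok], b[ok]); to <- c(to, b[ok], a[ok])
  }
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]
  deg <- tabulate(from, nbins = n)
  indptr <- c(0L, cumsum(deg))
  indices <- to - 1L

  nodes <- tibble::tibble(
    id = seq_len(n),
    bx = (keep - 1L) %/% nby + 1L,
    by = (keep - 1L) %% nby + 1L,
    f_red = binned$f_red[keep],
    f_yellow = binned$f_yellow[keep],
    n_sites = binned$n_sites[keep],
    w = w[keep],
    p_red = binned$f_red[keep] / w[keep]
  )

  n_comp <- n_walk_components(indptr, indices, n)
  if (any(deg == 0) || n_comp > 1) {
    warning(sprintf(
      "walk graph has %d connected component(s)%s; walks are confined to their start's component",
      n_comp, if (any(deg == 0)) " (including isolated nodes)" else ""))
  }
  structure(list(nodes = nodes, indptr = as.integer(indptr),
                 indices = as.integer(indices), n_components = n_comp,
                 phi = binned_class_ratio(binned)),
            class = "walk_graph")
}

n_walk_components <- function(indptr, indices, n) {
  seen <- logical(n)
  comp <- 0L
  for (start in seq_len(n)) {
    if (seen[start]) next
    comp <- comp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- indices[(indptr[v] + 1L):indptr[v + 1L]] + 1L
      if (indptr[v + 1L] == indptr[v]) nb <- integer(0)
      fresh <- nb[!seen[nb]]
      seen[fresh] <- TRUE
      queue <- c(queue, fresh)
    }
  }
  comp
}

as_walk_graph <- function(x, target_bins = 3000L) {
  if (inherits(x, "walk_graph")) x else walk_graph(as_binned(x, target_bins))
}

pair_targets <- function(targets) {
  targets <- match.arg(targets, c("rr", "ry", "yr", "yy"), several.ok = TRUE)
  unique(targets)
}

# Aggregate a walk campaign into the requested class-pair means.  Start
# weighting: a node contributes to alpha-starts with weight f_alpha, so
# fractional bins count proportionally.
aggregate_campaign <- function(camp, nodes, targets) {
  per_node <- function(sum, ssq, cnt) {
    m <- ifelse(cnt > 0, sum / cnt, NA_real_)
    v <- ifelse(cnt > 1, pmax(0, (ssq - sum^2 / pmax(cnt, 1)) / (cnt - 1)) / cnt,
                NA_real_)
    list(mean = m, var_mean = v)
  }
  to_r <- per_node(camp$sum_r, camp$ssq_r, camp$cnt_r)
  to_y <- per_node(camp$sum_y, camp$ssq_y, camp$cnt_y)
  one <- function(pair) {
    alpha <- substr(pair, 1, 1)
    beta <- substr(pair, 2, 2)
    wts <- if (alpha == "r") nodes$f_red else nodes$f_yellow
    res <- if (beta == "r") to_r else to_y
    tr <- if (beta == "r") camp$trunc_r else camp$trunc_y
    cnt <- if (beta == "r") camp$cnt_r else camp$cnt_y
    ok <- wts > 0 & !is.na(res$mean)
    if (!any(ok)) {
      stop(sprintf("no finite first passage times for %s (class unreachable within max_steps?)", pair))
    }
    sw <- sum(wts[ok])
    tau <- sum(wts[ok] * res$mean[ok]) / sw
    se <- sqrt(sum((wts[ok] / sw)^2 * res$var_mean[ok], na.rm = TRUE))
    started <- wts > 0
    tibble::tibble(from = alpha, to = beta, tau = tau, se = se,
                   truncated = sum(tr[started]),
                   walks = sum(cnt[started]) + sum(tr[started]))
  }
  dplyr::bind_rows(lapply(targets, one))
}

run_campaign <- function(graph, p_red, config, targets) {
  need_r <- any(substr(targets, 2, 2) == "r")
  need_y <- any(substr(targets, 2, 2) == "y")
  max_steps <- config$max_steps
  if (is.null(max_steps)) max_steps <- 200 * nrow(graph$nodes)
  walk_campaign_cpp(graph$indptr, graph$indices, p_red,
                    config$walks_per_start, max_steps, need_r, need_y)
}

#' Estimate class mean first passage times by simulated walks
#'
#' For each coloured bin, `walks_per_start` random walks are launched and the
#' first passage time to each target class recorded (the start node is
#' excluded, so tau >= 1).  Per-start means are then averaged over starts of
#' the source class, weighted by the start's class fraction.
#'
#' @param x A [class_grid], `binned_pattern` or `walk_graph`.
#' @param config A [walk_config].
#' @param targets Which class pairs to estimate, a subset of
#'   `c("rr", "ry", "yr", "yy")`.
#' @return A tibble with one row per pair: `from`, `to`, `tau`, `se` (Monte
#'   Carlo standard error of the weighted mean), `truncated`, `walks`.
#' @examples
#' ryr <- class_grid(matrix(c("R", "Y", "R"), nrow = 1))
#' estimate_cmfpt(ryr, walk_config(walks_per_start = 500, seed = 1))
#' @export
estimate_cmfpt <- function(x, config = walk_config(),
                           targets = c("rr", "ry", "yr", "yy")) {
  targets <- pair_targets(targets)
  graph <- as_walk_graph(x)
  check_both_classes(graph)
  out <- with_seed_if(config$seed, {
    camp <- run_campaign(graph, graph$nodes$p_red, config, targets)
    aggregate_campaign(camp, graph$nodes, targets)
  })
  warn_truncation(out)
  out
}

check_both_classes <- function(graph) {
  if (sum(graph$nodes$f_red) <= 0 || sum(graph$nodes$f_yellow) <= 0) {
    stop("both classes must be present with positive total weight")
  }
}

warn_truncation <- function(tab) {
  frac <- sum(tab$truncated) / max(1, sum(tab$walks))
  if (frac > 0.01) {
    warning(sprintf("%.2f%% of walks exceeded max_steps and were discarded",
                    100 * frac))
  }
  invisible(frac)
}

#' Estimate null-model class mean first passage times
#'
#' The null model keeps the walk graph's connectivity but redistributes the
#' node classes uniformly at random: in each of `null_reps` realisations of
#' the colouring process every coloured node is assigned a fixed class, red
#' with probability equal to the global class ratio phi, and a full walk
#' campaign is run on that colouring.  The campaigns are averaged.  Holding
#' each realisation's labels fixed (rather than resampling a node's class on
#' every arrival) makes the null the exact counterpart of a pattern whose
#' colours are assigned independently at random, which therefore sits at
#' tau_tilde = 1.
#'
#' @inheritParams estimate_cmfpt
#' @return A tibble as in [estimate_cmfpt()] with `tau` averaged over
#'   replicate campaigns.
#' @export
null_cmfpt <- function(x, config = walk_config(),
                       targets = c("rr", "ry", "yr", "yy")) {
  targets <- pair_targets(targets)
  graph <- as_walk_graph(x)
  check_both_classes(graph)
  out <- with_seed_if(config$seed, null_campaigns(graph, config, targets))
  warn_truncation(out)
  out
}

null_campaigns <- function(graph, config, targets) {
  phi <- graph$phi
  n <- nrow(graph$nodes)
  reps <- lapply(seq_len(config$null_reps), function(i) {
    red <- logical(n)
    for (try in 1:100) {
      red <- runif(n) < phi
      if (any(red) && !all(red)) break
    }
    nodes_null <- graph$nodes
    nodes_null$f_red <- graph$nodes$w * red
    nodes_null$f_yellow <- graph$nodes$w * !red
    camp <- run_campaign(graph, as.numeric(red), config, targets)
    aggregate_campaign(camp, nodes_null, targets)
  })
  dplyr::bind_rows(reps) |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(
      tau = mean(.data$tau),
      se = sqrt(sum(.data$se^2)) / dplyr::n(),
      truncated = sum(.data$truncated),
      walks = sum(.data$walks),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(paste0(.data$from, .data$to), targets))
}

#' Exact class mean first passage times (hitting-time oracle)
#'
#' Solves the linear hitting-time system of the absorbing chain in which a
#' walker arriving at a node is absorbed with probability equal to that
#' node's target-class weight: h = 1 + P diag(1 - a) h, with P the uniform
#' neighbour transition matrix and a the per-node absorption probabilities.
#' Aggregation over starts matches [estimate_cmfpt()].  Intended as an
#' independent verification oracle on graphs small enough for a sparse
#' solve.
#'
#' @inheritParams estimate_cmfpt
#' @return A tibble with `from`, `to`, `tau`.
#' @examples
#' ryr <- class_grid(matrix(c("R", "Y", "R"), nrow = 1))
#' exact_cmfpt(ryr)
#' @export
exact_cmfpt <- function(x, targets = c("rr", "ry", "yr", "yy")) {
  targets <- pair_targets(targets)
  graph <- as_walk_graph(x)
  check_both_classes(graph)
  n <- nrow(graph$nodes)
  deg <- diff(graph$indptr)
  if (any(deg == 0)) stop("exact solver requires every node to have a neighbour")
  from <- rep(seq_len(n), deg)
  to <- graph$indices + 1L
  P <- Matrix::sparseMatrix(i = from, j = to, x = 1 / deg[from], dims = c(n, n))

  hit <- function(a) {
    M <- Matrix::Diagonal(n) - P %*% Matrix::Diagonal(x = 1 - a)
    h <- tryCatch(Matrix::solve(M, rep(1, n)),
                  error = function(e) stop("singular hitting-time system: target class unreachable from part of the graph"))
    as.numeric(h)
  }
  h_r <- if (any(substr(targets, 2, 2) == "r")) hit(graph$nodes$p_red) else NULL
  h_y <- if (any(substr(targets, 2, 2) == "y")) hit(1 - graph$nodes$p_red) else NULL

  one <- function(pair) {
    alpha <- substr(pair, 1, 1)
    beta <- substr(pair, 2, 2)
    wts <- if (alpha == "r") graph$nodes$f_red else graph$nodes$f_yellow
    h <- if (beta == "r") h_r else h_y
    tibble::tibble(from = alpha, to = beta,
                   tau = sum(wts * h) / sum(wts))
  }
  dplyr::bind_rows(lapply(targets, one))
}

#' Normalised class mean first passage times
#'
#' Computes raw CMFPT by simulated walks, the null-model CMFPT on the same
#' graph (classes redistributed at random, abundances preserved), and their
#' ratio: tau_tilde = tau / tau_null.  A pattern whose colours are assigned
#' independently at random sits at tau_tilde = 1; segregated patterns give
#' tau_tilde_ry >> 1, and the ratio tau_tilde_ry / tau_tilde_yr reflects
#' which class forms the larger clusters.
#'
#' @inheritParams estimate_cmfpt
#' @return A `cmfpt_result`: list with `tau` (tibble: `from`, `to`, `raw`,
#'   `null`, `tilde`, standard errors, truncation counts), `phi`,
#'   `n_nodes`, and the resolved `config`.  [tidy()] returns the tau table,
#'   [glance()] a one-row tibble with the phase-space coordinates.
#' @examples
#' res <- normalized_cmfpt(generate_random(20, 20, 0.5, seed = 1),
#'                         walk_config(walks_per_start = 200, seed = 2,
#'                                     null_reps = 2))
#' glance(res)
#' @export
normalized_cmfpt <- function(x, config = walk_config(),
                             targets = c("rr", "ry", "yr", "yy")) {
  targets <- pair_targets(targets)
  graph <- as_walk_graph(x)
  check_both_classes(graph)
  tab <- with_seed_if(config$seed, {
    raw <- aggregate_campaign(run_campaign(graph, graph$nodes$p_red, config,
                                           targets),
                              graph$nodes, targets)
    nul <- null_campaigns(graph, config, targets)
    dplyr::inner_join(
      dplyr::rename(raw, raw = "tau", raw_se = "se",
                    raw_truncated = "truncated", raw_walks = "walks"),
      dplyr::rename(nul, null = "tau", null_se = "se",
                    null_truncated = "truncated", null_walks = "walks"),
      by = c("from", "to"))
  })
  if (any(!is.finite(tab$null) | tab$null <= 0)) {
    stop("null CMFPT could not be estimated for some class pair")
  }
  tab$tilde <- tab$raw / tab$null
  res <- structure(list(
    tau = tab, phi = graph$phi, n_nodes = nrow(graph$nodes),
    truncated = sum(tab$raw_truncated) + sum(tab$null_truncated),
    config = config, targets = targets
  ), class = "cmfpt_result")
  warn_truncation(tibble::tibble(
    truncated = c(tab$raw_truncated, tab$null_truncated),
    walks = c(tab$raw_walks, tab$null_walks)))
  res
}

#' @exportS3Method base::print
print.cmfpt_result <- function(x, ...) {
  cat(sprintf("<cmfpt_result> %d walk-graph nodes, phi = %.4f\n",
              x$n_nodes, x$phi))
  print(x$tau[, c("from", "to", "raw", "null", "tilde")])
  invisible(x)
}

#' @rdname normalized_cmfpt
#' @param x A `cmfpt_result`.
#' @param ... Unused.
#' @export
tidy.cmfpt_result <- function(x, ...) x$tau

#' @rdname normalized_cmfpt
#' @export
glance.cmfpt_result <- function(x, ...) {
  g <- function(pair) {
    row <- x$tau[x$tau$from == substr(pair, 1, 1) &
                 x$tau$to == substr(pair, 2, 2), ]
    if (nrow(row)) row$tilde else NA_real_
  }
  tibble::tibble(
    tau_rr_tilde = g("rr"), tau_ry_tilde = g("ry"),
    tau_yr_tilde = g("yr"), tau_yy_tilde = g("yy"),
    ratio_ry_yr = g("ry") / g("yr"),
    phi = x$phi, n_nodes = x$n_nodes, truncated = x$truncated
  )
}

#' Phase-space plot of CMFPT measurements
#'
#' Plots patterns in the (tau_tilde_ry, tau_tilde_ry / tau_tilde_yr) plane,
#' coloured by class ratio.
#'
#' @param data A data frame with columns `tau_ry_tilde`, `tau_yr_tilde` and
#'   optionally `phi` (e.g. rows of [glance.cmfpt_result()] or a pattern
#'   library).
#' @return A ggplot object.
#' @export
plot_phase_space <- function(data) {
  if (!all(c("tau_ry_tilde", "tau_yr_tilde") %in% names(data))) {
    stop("`data` needs columns tau_ry_tilde and tau_yr_tilde")
  }
  df <- dplyr::mutate(data, ratio = .data$tau_ry_tilde / .data$tau_yr_tilde)
  aes <- if ("phi" %in% names(df)) {
    ggplot2::aes(x = .data$tau_ry_tilde, y = .data$ratio, colour = .data$phi)
  } else {
    ggplot2::aes(x = .data$tau_ry_tilde, y = .data$ratio)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "normalised CMFPT red → yellow",
                  y = "red→yellow / yellow→red ratio") +
    ggplot2::theme_minimal()
}
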