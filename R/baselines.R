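#' Quadrat Shannon entropy of a two-class pattern
#'
#' Tiles the grid into L x L quadrats, computes the mutant (red) frequency
#' p_i among the coloured cells of each quadrat, and evaluates
#' H = -(1/n) * sum_i \[p_i log2 p_i + (1 - p_i) log2(1 - p_i)\] with the
#' convention 0 log 0 = 0.  Because the value depends on where the quadrat
#' grid is anchored, H is computed for every (x, y) offset in 0..L-1 and the
#' minimum over offsets is returned.  H ranges from 0 for fully segregated
#' patterns to 1 for fully mixed patterns.
#'
#' @param grid A 2-D [class_grid].
#' @param quadrat Quadrat side L in cells (default 10).
#' @param sweep_offsets Sweep all L^2 grid offsets and take the minimum
#'   (default); `FALSE` evaluates the (0, 0) anchor only.
#' @param include_partial Also score the partial tiles created at the grid
#'   edges, with their actual cell counts.  The default (`FALSE`) scores
#'   complete L x L quadrats only, so that a maximally mixed checkerboard
#'   attains H = 1 at every offset; partial edge tiles as small as 1 x 1
#'   would otherwise pull the offset minimum below 1 even for fully mixed
#'   patterns.  Quadrats containing no coloured cells are always skipped.
#' @return The entropy H in \[0, 1\].
#' @examples
#' shannon_entropy(generate_column(54, 54, 0.5))      # fully segregated: 0
#' shannon_entropy(generate_checkerboard(54, 54))     # fully mixed: 1
#' @export
shannon_entropy <- function(grid, quadrat = 10L, sweep_offsets = TRUE,
                            include_partial = FALSE) {
  if (!inherits(grid, "class_grid")) stop("`grid` must be a class_grid")
  if (grid_depth(grid) > 1) stop("entropy is defined for 2-D grids")
  L <- as.integer(quadrat)
  if (L < 1) stop("`quadrat` must be >= 1")
  assert_two_class(grid)
  a <- grid_layer(grid)
  h <- nrow(a); w <- ncol(a)
  xs <- rep(seq_len(w), each = h)
  ys <- rep(seq_len(h), times = w)
  red <- as.vector(a) == RED
  col <- as.vector(a) != EMPTY

  offsets <- if (sweep_offsets) 0:(L - 1L) else 0L
  best <- Inf
  for (ox in offsets) {
    qx <- (xs - 1L + ox) %/% L
    for (oy in offsets) {
      qy <- (ys - 1L + oy) %/% L
      qid <- qx * ((h + 2L * L) %/% L + 1L) + qy + 1L
      n_col <- tabulate(qid[col], nbins = max(qid))
      n_red <- tabulate(qid[col & red], nbins = max(qid))
      keep <- n_col > 0
      if (!include_partial) {
        # a quadrat is complete iff its full L x L footprint lies inside
        ux <- (seq_along(n_col) - 1L) %/% (((h + 2L * L) %/% L) + 1L)
        uy <- (seq_along(n_col) - 1L) %% (((h + 2L * L) %/% L) + 1L)
        x0 <- ux * L - ox + 1L
        y0 <- uy * L - oy + 1L
        keep <- keep & x0 >= 1L & y0 >= 1L & (x0 + L - 1L) <= w & (y0 + L - 1L) <= h
      }
      p <- n_red[keep] / n_col[keep]
      best <- min(best, mean(binary_entropy(p)))
    }
  }
  best
}

binary_entropy <- function(p) {
  term <- function(z) ifelse(z > 0, z * log2(z), 0)
  -(term(p) + term(1 - p))
}

#' Mean shortest distance between cell classes
#'
#' Builds the von-Neumann adjacency graph over the coloured cells and
#' averages the shortest-path length (in edges) over all ordered pairs from
#' the source class to the target class; same-class means exclude self
#' pairs.  Each mean is normalised by its value under a null model in which
#' the coloured cells are relabelled independently at random with the
#' pattern's class ratio, averaged over `null_reps` relabellings.
#'
#' @param grid A 2-D [class_grid].
#' @param null_reps Number of null relabellings (default 10).
#' @param seed Optional seed for the null relabellings.
#' @return A tibble with one row per ordered class pair: `from`, `to`, `raw`,
#'   `null`, `tilde`.
#' @examples
#' mean_shortest_distance(generate_random(15, 15, 0.5, seed = 1),
#'                        null_reps = 3, seed = 2)
#' @export
mean_shortest_distance <- function(grid, null_reps = 10, seed = NULL) {
  if (!inherits(grid, "class_grid")) stop("`grid` must be a class_grid")
  if (grid_depth(grid) > 1) stop("MSD is defined for 2-D grids")
  assert_two_class(grid)
  a <- grid_layer(grid)
  h <- nrow(a); w <- ncol(a)
  col_idx <- which(a != EMPTY)
  n <- length(col_idx)
  node <- matrix(NA_integer_, h, w)
  node[col_idx] <- seq_len(n)

  edges <- NULL
  if (w > 1) {
    p <- node[, -w]; q <- node[, -1]; ok <- !is.na(p) & !is.na(q)
    edges <- rbind(edges, cbind(p[ok], q[ok]))
  }
  if (h > 1) {
    p <- node[-h, ]; q <- node[-1, ]; ok <- !is.na(p) & !is.na(q)
    edges <- rbind(edges, cbind(p[ok], q[ok]))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  if (igraph::count_components(g) > 1) {
    warning("coloured-cell graph is disconnected; pairs are averaged within components")
  }
  D <- igraph::distances(g)

  labels <- a[col_idx]
  pair_means <- function(labels) {
    r <- which(labels == RED); y <- which(labels == YELLOW)
    msd <- function(from, to, same) {
      sub <- D[from, to, drop = FALSE]
      if (same) sub[cbind(seq_along(from), seq_along(to))] <- Inf
      vals <- sub[is.finite(sub)]
      if (!length(vals)) return(NA_real_)
      mean(vals)
    }
    c(rr = msd(r, r, TRUE), ry = msd(r, y, FALSE),
      yr = msd(y, r, FALSE), yy = msd(y, y, TRUE))
  }

  raw <- pair_means(labels)
  phi <- mean(labels == RED)
  nulls <- with_seed_if(seed, {
    vapply(seq_len(null_reps), function(i) {
      lab <- NULL
      for (try in 1:100) {
        lab <- ifelse(runif(n) < phi, RED, YELLOW)
        if (any(lab == RED) && any(lab == YELLOW)) break
      }
      pair_means(lab)
    }, numeric(4))
  })
  null_mean <- rowMeans(nulls)
  tibble::tibble(
    from = substr(names(raw), 1, 1),
    to = substr(names(raw), 2, 2),
    raw = unname(raw),
    null = unname(null_mean),
    tilde = unname(raw / null_mean)
  )
}
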