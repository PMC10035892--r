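#' Downsample a pattern into fractional-class bins
#'
#' Aggregates a label grid into square bins of integer side `k`, with `k` the
#' smallest integer such that `ceiling(width / k) * ceiling(height / k)` does
#' not exceed `target_bins`.  Each bin records the fractions of red, yellow
#' and empty sites among its constituents, so class proportions are preserved
#' exactly; a random walker on the binned graph then samples a bin's class on
#' every arrival in proportion to its coloured fractions.  Grids that already
#' fit the budget are binned with `k = 1` (the identity).
#'
#' @param grid A 2-D [class_grid] (slice 3-D volumes first with [slice_3d()]).
#' @param target_bins Maximum number of bins (default 3000).
#' @return A `binned_pattern`: a list with matrices `f_red`, `f_yellow`,
#'   `f_empty`, `n_sites` (bins in rows = y, columns = x), the bin side `k`,
#'   and the source grid dimensions.
#' @examples
#' b <- downsample(generate_column(60, 50, 0.5))
#' b$k
#' @export
downsample <- function(grid, target_bins = 3000L) {
  if (!inherits(grid, "class_grid")) stop("`grid` must be a class_grid")
  if (grid_depth(grid) > 1) stop("downsample() operates on 2-D grids; use slice_3d() first")
  if (target_bins < 1) stop("`target_bins` must be >= 1")
  w <- grid_width(grid)
  h <- grid_height(grid)
  k <- 1L
  while (ceiling(w / k) * ceiling(h / k) > target_bins) k <- k + 1L
  nbx <- as.integer(ceiling(w / k))
  nby <- as.integer(ceiling(h / k))

  a <- grid_layer(grid)
  bx <- (rep(seq_len(w), each = h) - 1L) %/% k
  by <- (rep(seq_len(h), times = w) - 1L) %/% k
  bin <- bx * nby + by + 1L
  n_bins <- nbx * nby
  cnt <- function(lab) {
    tabulate(bin[as.vector(a) == lab], nbins = n_bins)
  }
  n_red <- cnt(RED)
  n_yel <- cnt(YELLOW)
  n_tot <- tabulate(bin, nbins = n_bins)
  shape <- function(v) matrix(v, nrow = nby, ncol = nbx)
  structure(list(
    f_red = shape(n_red / n_tot),
    f_yellow = shape(n_yel / n_tot),
    f_empty = shape((n_tot - n_red - n_yel) / n_tot),
    n_sites = shape(n_tot),
    k = k,
    target_bins = as.integer(target_bins),
    source_dim = c(height = h, width = w),
    adjacency = "von_neumann"
  ), class = "binned_pattern")
}

#' @exportS3Method base::print
print.binned_pattern <- function(x, ...) {
  cat(sprintf(
    "<binned_pattern> %d x %d bins (k = %d, %d coloured), phi = %s\n",
    ncol(x$f_red), nrow(x$f_red), x$k, sum(x$f_red + x$f_yellow > 0),
    format(round(binned_class_ratio(x), 4))
  ))
  invisible(x)
}

#' Class ratio of a binned pattern
#'
#' Computed from the coloured site mass carried by the bins, so it equals the
#' class ratio of the source grid exactly.
#'
#' @param binned A `binned_pattern`.
#' @return The class ratio in \[0, 1\].
#' @export
binned_class_ratio <- function(binned) {
  red <- sum(binned$f_red * binned$n_sites)
  yel <- sum(binned$f_yellow * binned$n_sites)
  if (red + yel <= 0) stop("empty pattern: no coloured mass")
  red / (red + yel)
}

# Coerce grids to binned patterns where an analysis accepts either; grids are
# cropped to their coloured bounding box before binning so the bin budget is
# spent on tissue rather than background.
as_binned <- function(x, target_bins = 3000L) {
  if (inherits(x, "binned_pattern")) return(x)
  if (inherits(x, "class_grid")) return(downsample(crop_pattern(x), target_bins))
  stop("expected a class_grid or binned_pattern")
}
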