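#' Two-class label grids
#'
#' A `class_grid` stores a 2-D (or 3-D) lattice of site labels with three
#' categories: `RED` (mutant cells), `YELLOW` (wild-type cells) and `EMPTY`
#' (background).  It is backed by an integer matrix (or 3-D array) with codes
#' 0 = empty, 1 = red, 2 = yellow; rows index y, columns index x, and the
#' third array dimension (if any) indexes z.
#'
#' @param labels An integer or character matrix/array.  Character input uses
#'   `"R"`, `"Y"` and `"."` (or `""`/`" "`) for red, yellow and empty.
#' @return A `class_grid` object.
#' @examples
#' g <- class_grid(matrix(c("R", "Y", "R"), nrow = 1))
#' class_ratio(g)
#' @export
class_grid <- function(labels) {
  if (is.character(labels)) {
    codes <- match(labels, c(".", "R", "Y")) - 1L
    codes[labels %in% c("", " ")] <- 0L
    if (anyNA(codes)) stop("unknown label characters; use 'R', 'Y' or '.'")
    labels <- array(codes, dim = dim(labels))
  }
  if (!is.numeric(labels)) stop("`labels` must be an integer or character array")
  labels <- array(as.integer(labels), dim = dim(labels))
  if (!all(labels %in% c(EMPTY, RED, YELLOW))) {
    stop("labels must be coded 0 (empty), 1 (red) or 2 (yellow)")
  }
  nd <- length(dim(labels))
  if (nd == 2) labels <- array(labels, dim = c(dim(labels), 1L))
  if (length(dim(labels)) != 3) stop("`labels` must be a 2-D matrix or 3-D array")
  structure(labels, class = "class_grid")
}

#' @exportS3Method base::print
print.class_grid <- function(x, ...) {
  d <- dim(x)
  cnt <- label_counts(x)
  cat(sprintf(
    "<class_grid> %d x %d%s sites: %d red, %d yellow, %d empty (phi = %s)\n",
    grid_width(x), grid_height(x),
    if (d[3] > 1) sprintf(" x %d", d[3]) else "",
    cnt[["red"]], cnt[["yellow"]], cnt[["empty"]],
    if (cnt[["red"]] + cnt[["yellow"]] > 0) {
      format(round(class_ratio(x), 4))
    } else "NA"
  ))
  invisible(x)
}

#' @rdname class_grid
#' @param x A `class_grid`.
#' @export
grid_width <- function(x) dim(x)[2]

#' @rdname class_grid
#' @export
grid_height <- function(x) dim(x)[1]

#' @rdname class_grid
#' @export
grid_depth <- function(x) dim(x)[3]

# one z-plane as a plain matrix (guarding against 1-row dimension dropping)
grid_layer <- function(grid, z = 1) {
  matrix(unclass(grid)[, , z], nrow = dim(grid)[1])
}

label_counts <- function(x) {
  tab <- tabulate(unclass(x) + 1L, nbins = 3L)
  c(empty = tab[1], red = tab[2], yellow = tab[3])
}

assert_two_class <- function(grid) {
  cnt <- label_counts(grid)
  if (cnt[["red"]] < 1 || cnt[["yellow"]] < 1) {
    stop("pattern must contain at least one red and one yellow site")
  }
  invisible(cnt)
}

#' Class ratio of a pattern
#'
#' The fraction of coloured sites that are red (mutant):
#' phi = N_r / (N_r + N_y).  Background sites are excluded from both counts.
#'
#' @param grid A [class_grid].
#' @return The class ratio, a number in \[0, 1\].
#' @export
class_ratio <- function(grid) {
  cnt <- label_counts(grid)
  tot <- cnt[["red"]] + cnt[["yellow"]]
  if (tot < 1) stop("empty pattern: no coloured sites")
  unname(cnt[["red"]] / tot)
}

#' Swap the red and yellow classes of a pattern
#'
#' @param grid A [class_grid].
#' @return A [class_grid] with red and yellow interchanged.
#' @export
swap_classes <- function(grid) {
  out <- unclass(grid)
  red <- out == RED
  out[out == YELLOW] <- RED
  out[red] <- YELLOW
  class_grid(out)
}

#' Crop a pattern to the bounding box of its coloured sites
#'
#' @param grid A [class_grid].
#' @return A [class_grid] trimmed to the smallest axis-aligned box containing
#'   every red or yellow site.
#' @export
crop_pattern <- function(grid) {
  a <- unclass(grid)
  col <- a != EMPTY
  if (!any(col)) stop("empty pattern: no coloured sites")
  idx <- which(col, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2]); zz <- range(idx[, 3])
  class_grid(a[rr[1]:rr[2], cc[1]:cc[2], zz[1]:zz[2], drop = FALSE])
}

#' Extract a masked sub-region of a pattern
#'
#' Sites outside the mask are set to background, and the result is cropped to
#' the mask's bounding box.  Intended for analysing manually delineated,
#' locally connected tumour regions within a larger image.
#'
#' @param grid A [class_grid] (2-D).
#' @param mask A logical matrix with the same dimensions as the grid.
#' @return A [class_grid].
#' @export
extract_subregion <- function(grid, mask) {
  a <- unclass(grid)
  if (!is.logical(mask)) stop("`mask` must be logical")
  if (!identical(dim(mask), dim(a)[1:2])) {
    stop("mask dimensions must equal grid dimensions")
  }
  if (!any(mask)) stop("empty mask")
  out <- a
  out[, , 1][!mask] <- EMPTY
  idx <- which(mask, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  class_grid(out[rr[1]:rr[2], cc[1]:cc[2], 1, drop = FALSE])
}

#' Extract a 2-D slice from a 3-D pattern
#'
#' Emulates taking a planar tissue section through a simulated 3-D tumour:
#' the cross-section orthogonal to the given axis is returned with labels
#' preserved.
#'
#' @param grid A [class_grid] with depth > 1 (axis `"x"`/`"y"`) or any grid
#'   (axis `"z"`).
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param index 1-based position of the slicing plane along `axis`.
#' @return A 2-D [class_grid].
#' @export
slice_3d <- function(grid, axis = c("z", "x", "y"), index) {
  axis <- match.arg(axis)
  a <- unclass(grid)
  d <- dim(a)
  extent <- switch(axis, x = d[2], y = d[1], z = d[3])
  if (index < 1 || index > extent) {
    stop(sprintf("slice index %d out of range 1..%d on axis %s", index, extent, axis))
  }
  sl <- switch(axis,
    x = a[, index, , drop = FALSE],
    y = a[index, , , drop = FALSE],
    z = a[, , index, drop = FALSE]
  )
  # collapse the sliced axis so the result is a plain 2-D grid
  m <- switch(axis,
    x = matrix(sl, nrow = d[1], ncol = d[3]),
    y = matrix(sl, nrow = d[3], ncol = d[2], byrow = TRUE),
    z = matrix(sl, nrow = d[1], ncol = d[2])
  )
  class_grid(m)
}

#' Tabulate a pattern as a tibble of sites
#'
#' @param x A [class_grid].
#' @param ... Unused.
#' @return A tibble with columns `x`, `y` (and `z` for 3-D grids) and `label`
#'   (factor: empty/red/yellow).
#' @export
tidy.class_grid <- function(x, ...) {
  d <- dim(x)
  out <- tibble::tibble(
    x = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    y = rep(seq_len(d[1]), times = d[2] * d[3]),
    z = rep(seq_len(d[3]), each = d[1] * d[2]),
    label = factor(c("empty", "red", "yellow")[as.vector(unclass(x)) + 1L],
                   levels = c("empty", "red", "yellow"))
  )
  if (d[3] == 1) out$z <- NULL
  out
}

#' Plot a two-class pattern
#'
#' @param object A [class_grid] (3-D grids are shown slice by slice via
#'   facets).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.class_grid <- function(object, ...) {
  df <- tidy.class_grid(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      empty = "grey95", red = "#d7191c", yellow = "#ffd700")) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (!is.null(df$z)) p <- p + ggplot2::facet_wrap(~z)
  p
}
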