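#' Text-grid pattern format
#'
#' A plain-text interchange format for label grids: a header line
#' `width height [depth]`, then one character per site (`R` red, `Y` yellow,
#' `.` empty) per line, one line per grid row (rows of consecutive z-planes
#' are stacked for 3-D grids).
#'
#' @param grid A [class_grid].
#' @param path File path.
#' @return `read_grid()` returns a [class_grid]; `write_grid()` returns
#'   `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".txt")
#' write_grid(generate_column(6, 4, 0.5), p)
#' read_grid(p)
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "class_grid"))
  a <- unclass(grid)
  d <- dim(a)
  header <- if (d[3] > 1) paste(d[2], d[1], d[3]) else paste(d[2], d[1])
  chars <- c(".", "R", "Y")
  lines <- character(d[1] * d[3])
  li <- 1L
  for (z in seq_len(d[3])) {
    for (y in seq_len(d[1])) {
      lines[li] <- paste(chars[a[y, , z] + 1L], collapse = "")
      li <- li + 1L
    }
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file")
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) < 2 || anyNA(hdr)) stop("malformed header; expected 'width height [depth]'")
  w <- hdr[1]; h <- hdr[2]; d <- if (length(hdr) >= 3) hdr[3] else 1L
  body <- lines[-1]
  if (length(body) < h * d) stop("fewer rows than the header promises")
  a <- array(EMPTY, dim = c(h, w, d))
  li <- 1L
  for (z in seq_len(d)) {
    for (y in seq_len(h)) {
      ch <- strsplit(body[li], "")[[1]]
      if (length(ch) != w) stop(sprintf("row %d has %d sites, expected %d", li, length(ch), w))
      a[y, , z] <- match(ch, c(".", "R", "Y")) - 1L
      li <- li + 1L
    }
  }
  if (anyNA(a)) stop("unknown label characters; use 'R', 'Y' or '.'")
  class_grid(a)
}

#' Colour map for raster patterns
#'
#' Reference colours used to classify raster pixels into the two cell
#' classes.  A pixel whose RGB distance to a reference colour is within
#' `tolerance` takes that class; everything else is background.
#'
#' @param red,yellow RGB reference colours in \[0, 1\] (length-3).
#' @param tolerance Maximum Euclidean RGB distance for a match.
#' @param empty RGB colour used for background when writing.
#' @return A `colour_map` list.
#' @export
colour_map <- function(red = c(1, 0, 0), yellow = c(1, 1, 0),
                       tolerance = 0.25, empty = c(1, 1, 1)) {
  stopifnot(length(red) == 3, length(yellow) == 3, length(empty) == 3,
            tolerance >= 0)
  if (all(red == yellow)) stop("reference colours must be distinct")
  structure(list(red = red, yellow = yellow, tolerance = tolerance,
                 empty = empty), class = "colour_map")
}

#' Read / write patterns as raster images or text grids
#'
#' `read_pattern()` dispatches on the file extension: `.png` / `.tif(f)`
#' rasters are classified pixel by pixel against the colour map (nearest
#' reference colour within tolerance, everything else background); other
#' extensions are parsed as text grids.  `write_pattern()` writes PNG/TIFF
#' rasters using the map's reference colours, or the text format.
#'
#' @param path File path (`.png`, `.tif`/`.tiff`, or text grid).
#' @param map A [colour_map].
#' @param grid A [class_grid] (for writing).
#' @return `read_pattern()` returns a [class_grid].
#' @export
read_pattern <- function(path, map = colour_map()) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("reading TIFF needs the 'tiff' package")
    img <- tiff::readTIFF(path)
  } else {
    return(read_grid(path))
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  rgb <- img[, , 1:3, drop = FALSE]
  d_red <- sqrt((rgb[, , 1] - map$red[1])^2 + (rgb[, , 2] - map$red[2])^2 +
                (rgb[, , 3] - map$red[3])^2)
  d_yel <- sqrt((rgb[, , 1] - map$yellow[1])^2 + (rgb[, , 2] - map$yellow[2])^2 +
                (rgb[, , 3] - map$yellow[3])^2)
  lab <- matrix(EMPTY, nrow(d_red), ncol(d_red))
  lab[d_red <= map$tolerance & d_red <= d_yel] <- RED
  lab[d_yel <= map$tolerance & d_yel < d_red] <- YELLOW
  if (!any(lab != EMPTY)) stop("no pixels matched the colour map")
  class_grid(lab)
}

#' @rdname read_pattern
#' @export
write_pattern <- function(grid, path, map = colour_map()) {
  stopifnot(inherits(grid, "class_grid"))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "tif", "tiff")) return(write_grid(grid, path))
  if (grid_depth(grid) > 1) stop("raster output is 2-D; slice 3-D grids first")
  a <- grid_layer(grid)
  h <- nrow(a); w <- ncol(a)
  img <- array(0, dim = c(h, w, 3))
  pal <- rbind(map$empty, map$red, map$yellow)
  for (ch in 1:3) img[, , ch] <- matrix(pal[a + 1L, ch], h, w)
  if (ext == "png") {
    png::writePNG(img, path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("writing TIFF needs the 'tiff' package")
    tiff::writeTIFF(img, path)
  }
  invisible(path)
}

#' Write a deterministic battery of example patterns
#'
#' Produces the small fixture set used by the documentation and tests: toy
#' rows, 54 x 54 artificial patterns (segregated, checkerboard, clusters,
#' centred, column), three small simulated tumours and a mini pattern
#' library, plus a manifest TSV listing each file with its class ratio.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; the same seed reproduces the set byte for byte.
#' @param library_rows Approximate number of mini-library rows (default 200).
#' @return The manifest tibble, invisibly; written as `manifest.tsv`.
#' @export
make_fixtures <- function(out_dir, seed = 1, library_rows = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  put <- function(grid, name) {
    path <- file.path(out_dir, name)
    write_grid(grid, path)
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      file = name, width = grid_width(grid), height = grid_height(grid),
      phi = class_ratio(grid))
  }
  put(class_grid(matrix(c("R", "Y", "R"), nrow = 1)), "toy_ryr.txt")
  put(class_grid(matrix(c("R", "Y"), nrow = 1)), "toy_ry.txt")
  put(generate_column(54, 54, 0.5), "segregated_54.txt")
  put(generate_checkerboard(54, 54), "checkerboard_54.txt")
  put(generate_clusters(54, 54, 0.3, cluster_radius = 3, seed = seed),
      "clusters_54.txt")
  put(generate_centred(54, 54, 0.3), "centred_54.txt")
  put(generate_column(54, 54, 0.3), "column_54.txt")
  for (i in 1:3) {
    sim <- simulate_tumour(sim_params(s = c(0, 1, 3)[i], n_mut = 0.1, q = 5,
                                      n_max = 500, seed = seed + i))
    put(crop_pattern(sim$grid), sprintf("tumour_%d.txt", i))
  }
  reps <- max(1L, as.integer(round(library_rows / 8)))
  lib <- build_library(
    default_param_grid(s = c(0, 3), n_mut = c(0.01, 0.5), q = c(0, 20)),
    reps_per_combo = reps, base_seed = seed, n_max = 500, target_bins = 300,
    config = walk_config(walks_per_start = 100, null_reps = 2))
  write_library(lib, file.path(out_dir, "mini_library.tsv"))
  man <- dplyr::bind_rows(manifest)
  write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(man)
}
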