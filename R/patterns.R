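#' Artificial two-class mixing patterns
#'
#' Three reference pattern families spanning weak to complete segregation of
#' the two classes at a controlled class ratio `phi`:
#'
#' * `generate_clusters()`: a yellow background seeded with fixed-radius red
#'   discs (overlap allowed) at uniformly random centres, added one at a time
#'   until the realised class ratio first reaches or exceeds `phi`.
#' * `generate_centred()`: a single red disc at the grid centre containing
#'   exactly `round(phi * width * height)` sites; sites are ranked by
#'   Euclidean distance from the centre with ties broken in row-major order,
#'   making the output deterministic.
#' * `generate_column()`: the leftmost `round(phi * width)` columns red, the
#'   rest yellow --- a fully segregated pattern with a straight interface.
#' * `generate_random()`: every site independently red with probability
#'   `phi`, else yellow; this pattern coincides in distribution with the null
#'   model used to normalise first passage times.
#' * `generate_checkerboard()`: alternating red/yellow sites, the maximally
#'   mixed deterministic pattern.
#'
#' @param width,height Grid dimensions in cells.
#' @param phi Target class ratio (fraction of coloured sites that are red),
#'   in \[0, 1\].
#' @param cluster_radius Disc radius in cells for the clusters model.
#' @param seed Optional integer seed; identical arguments and seed give
#'   identical grids.
#' @return A [class_grid].
#' @examples
#' g <- generate_centred(10, 10, 0.25)
#' class_ratio(g)
#' @name patterns
NULL

check_phi <- function(phi) {
  if (!is.numeric(phi) || length(phi) != 1 || is.na(phi) || phi < 0 || phi > 1) {
    stop("`phi` must be a single number in [0, 1]")
  }
}

# round-half-up; base round() rounds half to even, which would make
# phi-controlled counts asymmetric around 0.5
round_half_up <- function(x) floor(x + 0.5)

#' @rdname patterns
#' @export
generate_clusters <- function(width, height, phi, cluster_radius = 3,
                              seed = NULL) {
  check_phi(phi)
  if (cluster_radius <= 0) stop("`cluster_radius` must be positive")
  if (cluster_radius > min(width, height) / 2) {
    stop("`cluster_radius` larger than min(width, height) / 2")
  }
  m <- matrix(YELLOW, nrow = height, ncol = width)
  n_sites <- width * height
  if (phi > 0) {
    with_seed_if(seed, {
      xs <- matrix(rep(seq_len(width), each = height), nrow = height)
      ys <- matrix(rep(seq_len(height), times = width), nrow = height)
      while (sum(m == RED) / n_sites < phi) {
        cx <- runif(1, 0.5, width + 0.5)
        cy <- runif(1, 0.5, height + 0.5)
        disc <- (xs - cx)^2 + (ys - cy)^2 <= cluster_radius^2
        m[disc] <- RED
      }
    })
  }
  class_grid(m)
}

#' @rdname patterns
#' @export
generate_centred <- function(width, height, phi) {
  check_phi(phi)
  n_red <- round_half_up(phi * width * height)
  xs <- rep(seq_len(width), each = height)
  ys <- rep(seq_len(height), times = width)
  cx <- (width + 1) / 2
  cy <- (height + 1) / 2
  d2 <- (xs - cx)^2 + (ys - cy)^2
  # row-major order = ascending y then x; the column-major site index is the
  # documented deterministic tie-break
  ord <- order(d2, ys, xs)
  m <- matrix(YELLOW, nrow = height, ncol = width)
  idx <- (xs - 1L) * height + ys
  if (n_red > 0) m[idx[ord[seq_len(n_red)]]] <- RED
  class_grid(m)
}

#' @rdname patterns
#' @export
generate_column <- function(width, height, phi) {
  check_phi(phi)
  n_red_cols <- round_half_up(phi * width)
  m <- matrix(YELLOW, nrow = height, ncol = width)
  if (n_red_cols > 0) m[, seq_len(n_red_cols)] <- RED
  class_grid(m)
}

#' @rdname patterns
#' @export
generate_random <- function(width, height, phi = 0.5, seed = NULL) {
  check_phi(phi)
  with_seed_if(seed, {
    m <- matrix(ifelse(runif(width * height) < phi, RED, YELLOW),
                nrow = height, ncol = width)
  })
  class_grid(m)
}

#' @rdname patterns
#' @export
generate_checkerboard <- function(width, height) {
  xs <- rep(seq_len(width), each = height)
  ys <- rep(seq_len(height), times = width)
  m <- matrix(ifelse((xs + ys) %% 2 == 0, RED, YELLOW), nrow = height)
  class_grid(m)
}
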