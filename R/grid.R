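#' Build a latent grid of equispaced states
#'
#' The latent n-space is a Cartesian product of equispaced points along each
#' of `n` axes, the simplest ground-truth model of a conformational state
#' space: each point stands for one conformer, and distances between points
#' stand in for distances between states.
#'
#' @param n Intrinsic dimensionality, 1, 2 or 3.
#' @param counts Integer vector of length `n`: points per axis.
#' @param lengths Numeric vector of length `n`: side length per axis, in
#'   dimensionless latent units.
#' @param mask Either `"full"` or `octagonal_mask(cut_depth)` (2D only),
#'   which removes triangular corner sets of states.
#' @return An object of class `latent_grid` with elements `coords` (M x n
#'   matrix), `cm_index` (M x n matrix of 0-based per-axis step indices),
#'   `n`, `counts`, `lengths`, `mask`.  Ordering is CM_1-major: the first
#'   axis index varies slowest.
#' @examples
#' g <- make_latent_grid(2, c(20, 20), c(1, 1.1))
#' nrow(g$coords)  # 400
#' @export
make_latent_grid <- function(n, counts, lengths, mask = "full") {
  if (!n %in% 1:3) stop_invalid("n must be 1, 2 or 3 (got %s)", n)
  counts <- as.integer(counts)
  if (length(counts) != n || length(lengths) != n) {
    stop_invalid("counts and lengths must each have %d entries", n)
  }
  if (any(counts <= 0) || any(lengths <= 0)) {
    stop_invalid("counts and lengths must be positive")
  }
  ax <- lapply(seq_len(n), function(k) {
    if (counts[k] == 1L) 0 else seq(0, lengths[k], length.out = counts[k])
  })
  idx_ax <- lapply(counts, function(ck) seq_len(ck) - 1L)
  # CM_1-major: first axis varies slowest -> expand over reversed axes
  cm_index <- as.matrix(expand.grid(rev(idx_ax), KEEP.OUT.ATTRS = FALSE))
  cm_index <- matrix(as.integer(cm_index[, rev(seq_len(n))]),
                     ncol = n, dimnames = list(NULL,
                                               paste0("cm", seq_len(n))))
  coords <- vapply(seq_len(n), function(k) ax[[k]][cm_index[, k] + 1L],
                   numeric(nrow(cm_index)))
  coords <- matrix(coords, ncol = n,
                   dimnames = list(NULL, paste0("x", seq_len(n))))
  g <- structure(list(coords = coords, cm_index = cm_index, n = n,
                      counts = counts, lengths = lengths, mask = "full"),
                 class = "latent_grid")
  if (!identical(mask, "full")) {
    if (!inherits(mask, "octagonal_mask")) {
      stop_invalid("unsupported mask; use \"full\" or octagonal_mask()")
    }
    g <- apply_octagonal_mask(g, mask$cut_depth)
  }
  g
}

#' Octagonal boundary mask specification
#'
#' @param cut_depth Non-negative integer: at each corner of a 2D grid,
#'   states with grid offsets `(i, j)` from that corner satisfying
#'   `i + j < cut_depth` are removed.
#' @return An object of class `octagonal_mask`.
#' @export
octagonal_mask <- function(cut_depth) {
  cut_depth <- as.integer(cut_depth)
  if (cut_depth < 0) stop_invalid("cut_depth must be >= 0")
  structure(list(cut_depth = cut_depth), class = "octagonal_mask")
}

#' Cut the four corners of a 2D state space
#'
#' Removes, at each corner, the triangular set of states whose grid offsets
#' `(i, j)` from that corner satisfy `i + j < cut_depth`, turning the
#' rectangular boundary into an octagon.  Works on a `latent_grid` or a
#' `conformer_ensemble` whose states form a 2D grid; the ordering of the
#' surviving states is preserved.
#'
#' @param x A `latent_grid` or `conformer_ensemble` with a 2D state space.
#' @param cut_depth Corner depth (see [octagonal_mask()]).
#' @return An object of the same class restricted to surviving states.
#' @export
apply_octagonal_mask <- function(x, cut_depth) {
  cut_depth <- as.integer(cut_depth)
  cm <- if (inherits(x, "latent_grid")) x$cm_index else
        if (inherits(x, "conformer_ensemble")) x$cm_coords else
        stop_invalid("unsupported input of class %s", class(x)[1])
  if (ncol(cm) != 2) stop_invalid("octagonal mask requires a 2D state space")
  counts <- apply(cm, 2, max) + 1L
  if (cut_depth >= min(counts) / 2) {
    stop_invalid("cut_depth must be < min(counts)/2")
  }
  keep <- octagon_keep(cm, counts, cut_depth)
  if (inherits(x, "latent_grid")) {
    x$coords <- x$coords[keep, , drop = FALSE]
    x$cm_index <- x$cm_index[keep, , drop = FALSE]
    x$mask <- sprintf("octagonal(%d)", cut_depth)
  } else {
    x$structures <- x$structures[keep]
    x$cm_coords <- x$cm_coords[keep, , drop = FALSE]
    x$angles <- x$angles[keep, , drop = FALSE]
    x$mask <- sprintf("octagonal(%d)", cut_depth)
  }
  x
}

octagon_keep <- function(cm, counts, cut_depth) {
  i <- cm[, 1]; j <- cm[, 2]
  ri <- counts[1] - 1L - i; rj <- counts[2] - 1L - j
  !(i + j < cut_depth | i + rj < cut_depth |
    ri + j < cut_depth | ri + rj < cut_depth)
}

#' @export
print.latent_grid <- function(x, ...) {
  cat(sprintf("latent_grid: n=%d, %s points (%s), mask=%s\n",
              x$n, nrow(x$coords), paste(x$counts, collapse = "x"), x$mask))
  invisible(x)
}
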