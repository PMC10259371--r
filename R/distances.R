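#' Pairwise Euclidean distance matrix
#'
#' The standard metric used for latent coordinates, flattened voxel maps
#' and flattened pixel images alike: `D_ij = ||a_i - a_j||_2`.
#'
#' @param x Numeric matrix (rows = states), a `latent_grid`, a
#'   `density_map` list/stack, or a `projection_set`.
#' @param tag Datatype tag recorded on the result: one of `"latent"`,
#'   `"acs"`, `"edm"`, `"pd"`.
#' @return An M x M `distance_matrix` (symmetric, zero diagonal) with
#'   attribute `datatype`.
#' @export
euclidean_distance_matrix <- function(x, tag = "latent") {
  X <- if (inherits(x, "latent_grid")) x$coords
  else if (inherits(x, "projection_set")) {
    t(apply(x$images, 3, as.numeric))
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "density_map"))) {
    t(vapply(x, function(m) as.numeric(m$voxels),
             numeric(length(x[[1]]$voxels))))
  } else as.matrix(x)
  if (!is.numeric(X)) stop_invalid("input must be numeric")
  # crossprod route: fast for wide feature matrices (voxels, pixels)
  r <- rowSums(X^2)
  D2 <- outer(r, r, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  D[cbind(seq_len(nrow(D)), seq_len(nrow(D)))] <- 0
  D <- (D + t(D)) / 2
  structure(D, datatype = tag, class = c("distance_matrix", "matrix"))
}

#' Pairwise RMSD distance matrix of an ensemble
#'
#' Root-mean-square deviation over atoms without any superposition:
#' `RMSD(A, B) = sqrt(sum_k ||a_k - b_k||^2 / m)`, which equals
#' `m^{-1/2}` times the Euclidean distance between the flattened
#' coordinate vectors.
#'
#' @param ensemble A `conformer_ensemble` (all structures share `m` and
#'   atom ordering).
#' @return An M x M `distance_matrix` with datatype `"acs"`.
#' @export
rmsd_distance_matrix <- function(ensemble) {
  ms <- vapply(ensemble$structures, function(s) nrow(s$coords), integer(1))
  if (length(unique(ms)) != 1) stop_invalid("structures differ in atom count")
  m <- ms[1]
  X <- ensemble_matrix(ensemble)
  D <- euclidean_distance_matrix(X, tag = "acs") / sqrt(m)
  structure(D, datatype = "acs", class = c("distance_matrix", "matrix"))
}

#' Row profile of a distance matrix
#'
#' The paper-style fingerprint of a metric space: the distances from one
#' reference state to all states, in state order.
#'
#' @param D A `distance_matrix`.
#' @param row Reference state index.
#' @return Numeric vector `D[row, ]`.
#' @export
distance_profile <- function(D, row = 1) {
  if (row < 1 || row > nrow(D)) stop_invalid("row out of range")
  as.numeric(D[row, ])
}

#' Similarity of two distance profiles
#'
#' Pearson correlation over the shared state ordering.
#'
#' @param p,q Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
profile_similarity <- function(p, q) {
  if (length(p) != length(q)) stop_invalid("profile lengths differ")
  stats::cor(p, q)
}
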