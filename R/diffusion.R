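#' Diffusion-map embedding of a distance matrix
#'
#' Gaussian kernel `W_ij = exp(-D_ij^2 / (2 * epsilon))` with
#' density normalization `W / (q_i q_j)^alpha` (alpha = 1 recovers the
#' Laplace-Beltrami operator regardless of sampling density, so the
#' eigenvectors converge to LBO eigenfunctions on the data manifold),
#' row-normalized to a Markov matrix.  The eigenproblem is solved through
#' the symmetric conjugate of the Markov operator and converted back to
#' right eigenvectors, which are orthonormal under the stationary-measure
#' inner product.
#'
#' `Psi_0` (constant, eigenvalue 1) is kept in the output but analysis
#' indexing is 1-based past it: `Psi_1` is the leading non-trivial
#' eigenvector, matching the standard spectral-embedding notation.
#'
#' @param D A `distance_matrix` (or plain symmetric matrix).
#' @param epsilon Gaussian bandwidth (squared-distance units).
#' @param k Number of non-trivial eigenvectors to retain
#'   (default `min(M - 1, 30)`).
#' @param alpha Density-normalization exponent in `[0, 1]` (default 1).
#' @return An object of class `embedding`: `values` (length k+1,
#'   descending, `values[1] = 1`), `vectors` (M x (k+1), column 1 the
#'   trivial `Psi_0`; signs fixed so the first substantial loading of each
#'   column is positive), `method = "DM"`, `epsilon`, `alpha`.
#' @export
diffusion_map <- function(D, epsilon, k = NULL, alpha = 1) {
  D <- unclass(as.matrix(D))
  M <- nrow(D)
  if (is.null(k)) k <- min(M - 1L, 30L)
  if (k > M - 1) stop_invalid("k must be <= M - 1")
  if (epsilon <= 0) stop_invalid("epsilon must be positive")
  if (alpha < 0 || alpha > 1) stop_invalid("alpha must be in [0, 1]")
  W <- exp(-D^2 / (2 * epsilon))
  if (any(rowSums(W) - 1 < 1e-14)) {
    warning(sprintf(paste0("kernel numerically disconnected at epsilon = ",
                           "%.3g (some rows couple only to themselves); ",
                           "smallest off-diagonal row sum = %.3g"),
                    epsilon, min(rowSums(W) - 1)))
  }
  q <- rowSums(W)
  if (alpha > 0) W <- W / outer(q, q)^alpha
  q1 <- rowSums(W)
  S <- W / sqrt(outer(q1, q1))     # symmetric conjugate of the Markov matrix
  es <- eigen(S, symmetric = TRUE)
  keep <- seq_len(k + 1L)
  vals <- es$values[keep]
  # right eigenvectors of the Markov matrix; phi orthonormal => psi
  # orthonormal under the stationary measure
  psi <- es$vectors[, keep, drop = FALSE] / sqrt(q1)
  psi <- fix_signs(psi)
  structure(list(values = vals, vectors = psi, method = "DM",
                 epsilon = epsilon, alpha = alpha, k = k),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %s, M=%d, k=%d%s\n", x$method, nrow(x$vectors),
              x$k,
              if (!is.null(x$epsilon)) sprintf(", epsilon=%.4g", x$epsilon)
              else ""))
  invisible(x)
}

#' Extract analysis eigenvectors (1-based past the trivial one)
#'
#' @param embedding An `embedding`.
#' @param i Analysis index or indices (`Psi_i`, i >= 1).
#' @return Matrix of the requested eigenvectors.
#' @export
psi <- function(embedding, i) {
  embedding$vectors[, i + 1L, drop = FALSE]
}

#' Gaussian-bandwidth scan and estimate
#'
#' Scans epsilon over a logarithmic grid, records
#' `L(eps) = log sum_ij W_ij(eps)`, and returns the bandwidth at the point
#' of maximum slope of the log-log curve.  The curve is sigmoidal: flat at
#' both extremes (kernel = identity, kernel = all-ones) and rising in
#' between; the steepest point tracks the scale of typical neighbor
#' distances.
#'
#' @param D A `distance_matrix`.
#' @param n_eps Grid size (default 64).
#' @param range Optional length-2 epsilon range; defaults to
#'   `[min positive D^2 / 100, max D^2 * 100]`.
#' @return An object of class `bandwidth_scan`: `epsilons`,
#'   `log_kernel_sums`, `slopes`, `epsilon_hat`.
#' @export
estimate_bandwidth <- function(D, n_eps = 64, range = NULL) {
  D <- unclass(as.matrix(D))
  d2 <- D[upper.tri(D)]^2
  d2 <- d2[d2 > 0]
  if (!length(d2)) stop_invalid("degenerate distance matrix (all zero)")
  if (is.null(range)) range <- c(min(d2) / 100, max(d2) * 100)
  eps <- exp(seq(log(range[1]), log(range[2]), length.out = n_eps))
  ls <- vapply(eps, function(e) log(sum(exp(-D^2 / (2 * e)))), numeric(1))
  if (max(ls) - min(ls) < 1e-10) stop_invalid("flat kernel-sum curve")
  slopes <- diff(ls) / diff(log(eps))
  i <- which.max(slopes)
  structure(list(epsilons = eps, log_kernel_sums = ls, slopes = slopes,
                 epsilon_hat = sqrt(eps[i] * eps[i + 1])),
            class = "bandwidth_scan")
}

#' Bandwidth for a named regime
#'
#' The small regime sits a factor of three below the estimated bandwidth
#' (tracking the scale of the published regime markers relative to the
#' estimate on the same data), but never below a connectivity floor that
#' keeps the weakest nearest-neighbor kernel weight at `exp(-20)` or more
#' (much smaller bandwidths decouple the grid into near-independent
#' chains and scramble the leading eigenvectors).  The large regime is
#' ten times the squared diameter of the data, which is at least an order
#' of magnitude above the estimate and reaches the flat-kernel limit where
#' Legendre-like eigenfunctions appear on latent grids.
#'
#' @param D A `distance_matrix`.
#' @param regime `"small"`, `"large"` or `"auto"` (the estimate itself).
#' @param scan Optional precomputed `bandwidth_scan`.
#' @return Epsilon value.
#' @export
eps_regime <- function(D, regime = c("auto", "small", "large"), scan = NULL) {
  regime <- match.arg(regime)
  D <- unclass(as.matrix(D))
  if (is.null(scan)) scan <- estimate_bandwidth(D)
  eh <- scan$epsilon_hat
  switch(regime,
    auto = eh,
    small = {
      Dp <- D; diag(Dp) <- Inf
      floor_eps <- max(apply(Dp, 1, min))^2 / 40
      max(eh / 3, floor_eps)
    },
    large = max(10 * max(D)^2, 10 * eh)
  )
}

#' PCA embedding of a data matrix
#'
#' Mean-centered principal-component scores, packaged like a diffusion-map
#' embedding: a constant `Psi_0` column is prepended so analysis indexing
#' (`Psi_1`, `Psi_2`, ...) is shared between the two methods.
#'
#' @param X Numeric matrix, rows = states, columns = features.
#' @param k Number of components (reduced to the rank with a warning if
#'   too large).
#' @return An `embedding` with `method = "PCA"`; `values` holds `1`
#'   followed by the component variances scaled to `values[2] = lambda_1 <
#'   1`.
#' @export
pca_embed <- function(X, k = NULL) {
  X <- as.matrix(x_unwrap(X))
  M <- nrow(X)
  if (is.null(k)) k <- min(M - 1L, 30L)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  r <- sum(pr$sdev > pr$sdev[1] * 1e-10)
  if (k > r) {
    warning(sprintf("k reduced from %d to rank %d", k, r))
    k <- r
  }
  scores <- pr$x[, seq_len(k), drop = FALSE]
  scores <- sweep(scores, 2, sqrt(colSums(scores^2)), "/")
  vars <- pr$sdev[seq_len(k)]^2
  vecs <- fix_signs(cbind(1 / sqrt(M), scores))
  structure(list(values = c(1, vars / (sum(vars) + vars[1])),
                 vectors = vecs, method = "PCA", epsilon = NULL,
                 alpha = NULL, k = k),
            class = "embedding")
}

x_unwrap <- function(x) {
  if (inherits(x, "latent_grid")) return(x$coords)
  if (inherits(x, "conformer_ensemble")) return(ensemble_matrix(x))
  if (inherits(x, "projection_set")) return(t(apply(x$images, 3, as.numeric)))
  x
}

#' Export an embedding to CSV and JSON
#'
#' Writes the eigenvector matrix (row/column headers = state / Psi index)
#' as CSV and a JSON summary of eigenvalues and kernel settings.
#'
#' @param embedding An `embedding`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the summary list.
#' @export
export_embedding <- function(embedding, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    V <- embedding$vectors
    colnames(V) <- paste0("psi", seq_len(ncol(V)) - 1L)
    utils::write.csv(data.frame(state = seq_len(nrow(V)), V),
                     csv_path, row.names = FALSE)
  }
  summ <- list(method = embedding$method,
               eigenvalues = as.numeric(embedding$values),
               epsilon = embedding$epsilon, alpha = embedding$alpha,
               k = embedding$k)
  if (!is.null(json_path)) {
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(summ)
}
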