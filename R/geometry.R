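#' Ground-truth ordering of a state space
#'
#' The analysis here is a ground-truth laboratory: every state's position
#' along each conformational motion is known by construction, and the
#' spectral geometry is read off by indexing eigenvectors with that
#' knowledge.  For each CM this returns the normalized latent coordinate
#' `x` of every state in `[0, 1]`, the plotting permutation that sorts
#' states by that CM, and the "sweep" subset of states along the CM with
#' every other CM held at its first level.
#'
#' @param x A `latent_grid` or `conformer_ensemble`.
#' @return An object of class `gt_ordering`: a list with one element per
#'   CM, each holding `x` (length M), `perm` (length M), `sweep`
#'   (indices of the single-CM sweep in CM order).
#' @export
ground_truth_ordering <- function(x) {
  cm <- if (inherits(x, "latent_grid")) x$cm_index
  else if (inherits(x, "conformer_ensemble")) x$cm_coords
  else stop_invalid("need a latent_grid or conformer_ensemble")
  n <- ncol(cm)
  out <- lapply(seq_len(n), function(g) {
    rng <- range(cm[, g])
    xg <- if (diff(rng) == 0) rep(0, nrow(cm)) else
      (cm[, g] - rng[1]) / diff(rng)
    others <- setdiff(seq_len(n), g)
    at_base <- if (length(others)) {
      rowSums(cm[, others, drop = FALSE] !=
              matrix(apply(cm[, others, drop = FALSE], 2, min),
                     nrow(cm), length(others), byrow = TRUE)) == 0
    } else rep(TRUE, nrow(cm))
    sweep_idx <- which(at_base)[order(xg[at_base])]
    list(x = xg, perm = order(xg), sweep = sweep_idx)
  })
  structure(out, class = "gt_ordering", n = n)
}

# candidate mode table: all cosine products with indices <= max_mode
# (not all zero), plus Legendre products of the same indices
mode_candidates <- function(ordering, max_mode) {
  n <- attr(ordering, "n")
  grid <- as.matrix(expand.grid(rep(list(0:max_mode), n)))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  xs <- lapply(ordering, `[[`, "x")
  cand_cos <- apply(grid, 1, function(vw) {
    v <- rep(1, length(xs[[1]]))
    for (g in seq_len(n)) v <- v * cos(vw[g] * pi * xs[[g]])
    v
  })
  cand_leg <- apply(grid, 1, function(vw) {
    v <- rep(1, length(xs[[1]]))
    for (g in seq_len(n)) v <- v * legendre_mode(vw[g], xs[[g]])
    v
  })
  list(modes = grid, cosine = cand_cos, legendre = cand_leg)
}

#' Assign analytic mode indices to eigenvectors
#'
#' Correlates each analysis eigenvector against all candidate analytic
#' eigenfunctions (cosine products and Legendre products with component
#' indices up to `max_mode`), evaluated at each state's ground-truth
#' coordinates.  The best candidate is assigned when its absolute
#' correlation reaches `threshold`; otherwise the vector is labeled
#' `"mixed"` (a clear partial match, as produced by a degenerate or
#' misaligned admixture, which correlates at about 0.7 with either pure
#' target) or `"unclassified"`.
#'
#' @param embedding An `embedding`.
#' @param ordering A `gt_ordering`.
#' @param max_mode Largest component index considered (default 4).
#' @param threshold Absolute-correlation acceptance threshold
#'   (default 0.9).
#' @param n_vectors How many analysis eigenvectors to assign (default all
#'   retained).
#' @return A data.frame of class `mode_assignment`: columns `i`, mode
#'   indices `v` (,`w`, ...), `r` (|correlation|), `family`
#'   (`"cosine"`/`"legendre"`), `class` in `pure-CM`, `cross-term`,
#'   `legendre`, `mixed`, `unclassified`.
#' @export
assign_modes <- function(embedding, ordering, max_mode = 4, threshold = 0.9,
                         n_vectors = NULL) {
  M <- nrow(embedding$vectors)
  if (length(ordering[[1]]$x) != M) stop_invalid("ordering length mismatch")
  if (is.null(n_vectors)) n_vectors <- embedding$k
  n_vectors <- min(n_vectors, embedding$k)
  cand <- mode_candidates(ordering, max_mode)
  n <- attr(ordering, "n")
  res <- lapply(seq_len(n_vectors), function(i) {
    v <- psi(embedding, i)
    rc <- abs(suppressWarnings(stats::cor(v, cand$cosine)))[1, ]
    rl <- abs(suppressWarnings(stats::cor(v, cand$legendre)))[1, ]
    rc[is.na(rc)] <- 0; rl[is.na(rl)] <- 0
    bc <- which.max(rc); bl <- which.max(rl)
    if (rl[bl] > rc[bc]) {
      best <- bl; r <- rl[bl]; family <- "legendre"
    } else {
      best <- bc; r <- rc[bc]; family <- "cosine"
    }
    vw <- cand$modes[best, ]
    cls <- if (r < threshold) {
      if (r >= 0.5) "mixed" else "unclassified"
    } else if (family == "legendre") "legendre"
    else if (sum(vw > 0) == 1) "pure-CM"
    else "cross-term"
    c(list(i = i), as.list(vw), list(r = r, family = family, class = cls))
  })
  df <- do.call(rbind, lapply(res, function(z) as.data.frame(z)))
  names(df) <- c("i", c("v", "w", "u")[seq_len(n)], "r", "family", "class")
  class(df) <- c("mode_assignment", "data.frame")
  df
}

#' Flag (near-)degenerate consecutive eigenvalue pairs
#'
#' A Markov spectrum at small bandwidth is crowded just below 1, so the
#' pair gap is measured relative to the eigenvalue's distance below the
#' trivial eigenvalue (`1 - lambda_i`), which tracks the Laplacian
#' eigenvalue scale: a pair is flagged when
#' `|lambda_i - lambda_j| / (1 - lambda_i) < rel_tol`.
#'
#' @param values Eigenvalues sorted descending (an `embedding`'s
#'   non-trivial values, or the embedding itself).
#' @param rel_tol Relative gap below which a consecutive pair is flagged
#'   (default 1e-3).
#' @return 2-column matrix of analysis index pairs (i, j = i + 1).
#' @export
detect_degenerate_pairs <- function(values, rel_tol = 1e-3) {
  if (inherits(values, "embedding")) values <- values$values[-1]
  pairs <- NULL
  for (i in seq_len(length(values) - 1)) {
    gap <- abs(values[i] - values[i + 1]) /
      max(1 - values[i], .Machine$double.eps)
    if (is.finite(gap) && gap < rel_tol) pairs <- rbind(pairs, c(i, i + 1))
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  colnames(pairs) <- c("i", "j")
  pairs
}

# rotate a pair of vectors by theta (degrees): columns of cbind(v1,v2) %*% R
rotate_pair <- function(V, theta) {
  t_ <- deg2rad(theta)
  V %*% matrix(c(cos(t_), -sin(t_), sin(t_), cos(t_)), 2, 2)
}

# decoupling score of a rotated pair against two targets: best pairing of
# absolute correlations
pair_score <- function(V, t1, t2) {
  r11 <- abs(stats::cor(V[, 1], t1)); r22 <- abs(stats::cor(V[, 2], t2))
  r12 <- abs(stats::cor(V[, 1], t2)); r21 <- abs(stats::cor(V[, 2], t1))
  max(r11 + r22, r12 + r21)
}

#' Scan the rotation of an eigenvector pair against canonical targets
#'
#' Applies the 2 x 2 rotation `R(theta)` to the pair over a grid of
#' angles, scoring each angle by the best pairing of absolute
#' correlations with the two analytic target modes, and locates the
#' angles of maximal decoupling.
#'
#' @param pair M x 2 matrix (two eigenvectors spanning an approximately
#'   invariant subspace).
#' @param targets M x 2 matrix of analytic target modes.
#' @param thetas Angle grid in degrees (default `seq(0, 360, by 0.5)`,
#'   open at 360).
#' @return List with `thetas`, `scores`, `peaks` (angles of local maxima
#'   within 2% of the global maximum), `spacings` (successive differences
#'   of the peaks).
#' @export
rotation_scan <- function(pair, targets,
                          thetas = seq(0, 359.5, by = 0.5)) {
  scores <- vapply(thetas, function(th) {
    pair_score(rotate_pair(pair, th), targets[, 1], targets[, 2])
  }, numeric(1))
  n <- length(scores)
  prev <- c(scores[n], scores[-n]); nxt <- c(scores[-1], scores[1])
  is_peak <- scores >= prev & scores > nxt & scores >= max(scores) * 0.98
  peaks <- thetas[is_peak]
  spacings <- if (length(peaks) > 1) diff(peaks) else numeric(0)
  list(thetas = thetas, scores = scores, peaks = peaks,
       spacings = spacings)
}

#' Recover the rotation angle of a misaligned eigenvector pair
#'
#' Degenerate or misaligned eigenvector pairs are admixtures
#' `Psi_i = beta_1 psi_a + beta_2 psi_b` of two canonical modes, with
#' `beta_1 = cos(theta)`, `beta_2 = sin(theta)`.  The decoupling angle is
#' found by a 0.5-degree grid scan over `[0, 90)` followed by golden-
#' section refinement; post-rotation both members must match their pure
#' targets.
#'
#' @param pair M x 2 matrix of the eigenvector pair.
#' @param targets M x 2 matrix of the two analytic target modes.
#' @param threshold Per-vector absolute correlation that the rotated pair
#'   must reach (default 0.9); failure returns `success = FALSE` with the
#'   best score.
#' @return An object of class `misaligned_pair`: `theta` (degrees in
#'   `[0, 90)`), `beta` (`c(cos, sin)` of theta), `score` (sum of the two
#'   correlations), `correlations` (per-vector, after rotation and best
#'   pairing), `success`.
#' @export
recover_rotation <- function(pair, targets, threshold = 0.9) {
  f <- function(th) pair_score(rotate_pair(pair, th), targets[, 1],
                               targets[, 2])
  grid <- seq(0, 89.5, by = 0.5)
  s <- vapply(grid, f, numeric(1))
  i <- which.max(s)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-4)
  theta <- opt$maximum %% 90
  V <- rotate_pair(pair, opt$maximum)
  r11 <- abs(stats::cor(V[, 1], targets[, 1]))
  r22 <- abs(stats::cor(V[, 2], targets[, 2]))
  r12 <- abs(stats::cor(V[, 1], targets[, 2]))
  r21 <- abs(stats::cor(V[, 2], targets[, 1]))
  cors <- if (r11 + r22 >= r12 + r21) c(r11, r22) else c(r12, r21)
  structure(list(theta = theta,
                 beta = c(cos(deg2rad(theta)), sin(deg2rad(theta))),
                 score = sum(cors), correlations = cors,
                 success = all(cors >= threshold)),
            class = "misaligned_pair")
}

#' @export
print.misaligned_pair <- function(x, ...) {
  cat(sprintf("misaligned_pair: theta = %.2f deg, correlations %.3f/%.3f%s\n",
              x$theta, x$correlations[1], x$correlations[2],
              if (x$success) "" else " (below threshold)"))
  invisible(x)
}

#' Classify 2D eigenvector subspaces as Lissajous/Chebyshev curves
#'
#' For each CM, takes the leading pure eigenvector of that CM and pairs
#' it with deeper eigenvectors.  Along the CM's single-sweep ordering the
#' pair traces a Lissajous curve `L_{p,q}`; `p` and `q` are fitted by
#' correlation with `cos(p * pi * x)` / `cos(q * pi * x)`.  Pairs with
#' `q = 2p` lie on the Chebyshev parabola `T_2`; only `p = 1` maps the
#' conformational order bijectively, higher `p` are parabolic harmonics.
#'
#' @param embedding An `embedding`.
#' @param ordering A `gt_ordering`.
#' @param assignments Optional precomputed [assign_modes()] result.
#' @param max_pairs Deepest partner eigenvector considered per CM
#'   (default 10).
#' @param max_freq Largest Lissajous frequency fitted (default 6).
#' @param min_r Minimum fit correlation to report a pair (default 0.9).
#' @return data.frame with columns `cm`, `i`, `j`, `p`, `q`, `r_i`,
#'   `r_j`, `chebyshev` (`T_k` label or NA), `multiplicity`, `monotonic`,
#'   `t2_residual` (RMS of `y = 2x^2 - 1` on affinely normalized
#'   coordinates, for `q = 2p` pairs).
#' @export
classify_subspaces <- function(embedding, ordering, assignments = NULL,
                               max_pairs = 10, max_freq = 6, min_r = 0.9) {
  if (is.null(assignments)) {
    assignments <- assign_modes(embedding, ordering,
                                max_mode = max_freq)
  }
  n <- attr(ordering, "n")
  midx <- as.matrix(assignments[, c("v", "w", "u")[seq_len(n)], drop = FALSE])
  rows <- NULL
  for (g in seq_len(n)) {
    pure_g <- assignments$class == "pure-CM" & midx[, g] > 0
    if (!any(pure_g)) next
    lead <- min(assignments$i[pure_g])
    sw <- ordering[[g]]$sweep
    xs <- ordering[[g]]$x[sw]
    fit_freq <- function(vals) {
      rs <- vapply(seq_len(max_freq), function(p) {
        abs(stats::cor(vals, cos(p * pi * xs)))
      }, numeric(1))
      list(p = which.max(rs), r = max(rs))
    }
    a <- psi(embedding, lead)[sw, 1]
    fa <- fit_freq(a)
    partners <- setdiff(seq_len(min(embedding$k, max_pairs + lead)), lead)
    for (j in partners) {
      b <- psi(embedding, j)[sw, 1]
      fb <- fit_freq(b)
      if (fa$r < min_r || fb$r < min_r) next
      curve <- cbind(a, b)
      mult <- harmonic_multiplicity(curve)
      cheb <- if (fb$p %% fa$p == 0 && fb$p > fa$p)
        sprintf("T%d", fb$p / fa$p) else NA_character_
      t2res <- NA_real_
      if (!is.na(cheb) && fb$p == 2 * fa$p) {
        xn <- 2 * (a - min(a)) / (max(a) - min(a)) - 1
        yn <- 2 * (b - min(b)) / (max(b) - min(b)) - 1
        sgn <- sign(stats::cor(yn, 2 * xn^2 - 1))
        t2res <- sqrt(mean((sgn * yn - (2 * xn^2 - 1))^2))
      }
      rows <- rbind(rows, data.frame(
        cm = g, i = lead, j = j, p = fa$p, q = fb$p,
        r_i = fa$r, r_j = fb$r, chebyshev = cheb,
        multiplicity = mult, monotonic = mult == 1,
        t2_residual = t2res))
    }
  }
  if (is.null(rows)) {
    rows <- data.frame(cm = integer(0), i = integer(0), j = integer(0),
                       p = integer(0), q = integer(0), r_i = numeric(0),
                       r_j = numeric(0), chebyshev = character(0),
                       multiplicity = integer(0), monotonic = logical(0),
                       t2_residual = numeric(0))
  }
  rows
}

#' Harmonic multiplicity of a curve
#'
#' Number of maximal monotone segments of the first coordinate as a
#' function of the ordering index, after suppressing ripple below 1% of
#' the coordinate range.  Multiplicity 1 means the domain-to-curve map is
#' bijective (the leading parabola); higher values are parabolic
#' harmonics that repeat the conformational information.
#'
#' @param curve_points 2-column matrix of curve points, already in
#'   ground-truth order.
#' @param deadband Fraction of the first coordinate's range below which
#'   steps are treated as ties (default 0.01).
#' @return Integer multiplicity (>= 1).
#' @export
harmonic_multiplicity <- function(curve_points, deadband = 0.01) {
  xc <- curve_points[, 1]
  if (length(xc) < 3) stop_invalid("need at least 3 points")
  d <- diff(xc)
  d[abs(d) < deadband * diff(range(xc))] <- 0
  s <- sign(d)
  s <- s[s != 0]
  if (!length(s)) return(1L)
  as.integer(1L + sum(diff(s) != 0))
}

#' Spacing statistics along a curve
#'
#' Consecutive arclength spacings and their max/min ratio; quantifies the
#' nonuniform rates of change a Lissajous curve imposes on equispaced
#' states (dense near boundaries and vertex, sparse mid-limb).
#'
#' @param curve_points Matrix of ordered curve points (any dimension).
#' @return List with `spacings` and `ratio`.
#' @export
nonuniformity_profile <- function(curve_points) {
  P <- as.matrix(curve_points)
  if (nrow(P) < 3) stop_invalid("need at least 3 points")
  sp <- sqrt(rowSums((P[-1, , drop = FALSE] -
                      P[-nrow(P), , drop = FALSE])^2))
  list(spacings = sp, ratio = max(sp) / min(sp))
}

#' Export a spectral-geometry analysis report
#'
#' JSON report per embedding: eigenvalues, per-vector mode assignments,
#' misaligned pairs and the subspace-curve table, plus a CSV of
#' eigenvector traces reordered by each CM for plotting.
#'
#' @param embedding An `embedding`.
#' @param ordering A `gt_ordering`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @param ... Passed to [assign_modes()].
#' @return The report list, invisibly.
#' @export
export_analysis <- function(embedding, ordering, json_path = NULL,
                            csv_path = NULL, ...) {
  asg <- assign_modes(embedding, ordering, ...)
  deg <- detect_degenerate_pairs(embedding)
  curves <- classify_subspaces(embedding, ordering, assignments = asg)
  report <- list(
    eigenvalues = as.numeric(embedding$values),
    method = embedding$method, epsilon = embedding$epsilon,
    assignments = asg, degenerate_pairs = as.data.frame(deg),
    subspace_curves = curves)
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(csv_path)) {
    tr <- do.call(cbind, lapply(seq_along(ordering), function(g) {
      V <- embedding$vectors[ordering[[g]]$perm, -1, drop = FALSE]
      colnames(V) <- sprintf("cm%d_psi%d", g, seq_len(ncol(V)))
      V
    }))
    utils::write.csv(data.frame(rank = seq_len(nrow(tr)), tr), csv_path,
                     row.names = FALSE)
  }
  invisible(report)
}
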