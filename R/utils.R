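#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

#' Derive a child seed deterministically
#'
#' Mixes a base seed with integer tags (e.g. state and replicate indices)
#' into a new seed below 2^31.
#'
#' @param base_seed Integer base seed.
#' @param ... Integer tags.
#' @return Integer seed in `[0, 2^31)`.
#' @keywords internal
derive_seed <- function(base_seed, ...) {
  tags <- c(...)
  s <- as.double(base_seed) %% 2147483647
  for (t in tags) {
    s <- (s * 69069 + as.double(t) * 2654435761 + 1) %% 2147483647
  }
  as.integer(s)
}

# Fix eigenvector signs: first loading whose magnitude exceeds a relative
# floor is made positive.  Applied column-wise.
fix_signs <- function(V, tol = 1e-8) {
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    idx <- which(abs(v) > tol * max(abs(v)))
    if (length(idx) && v[idx[1]] < 0) V[, j] <- -v
  }
  V
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
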