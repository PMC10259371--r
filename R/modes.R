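#' Analytic Laplace-Beltrami eigenfunctions on the interval
#'
#' Neumann eigenfunctions of the interval `[0, 1]`: `cos(k * pi * x)`
#' (up to normalization); `k = 0` gives the constant function.
#'
#' @param k Mode index (>= 0).
#' @param x Points in `[0, 1]`.
#' @return Numeric vector of the same length as `x`.
#' @export
analytic_interval_mode <- function(k, x) {
  if (k < 0) stop_invalid("k must be >= 0")
  cos(k * pi * x)
}

#' Analytic eigenfunctions on a rectangle
#'
#' Neumann eigenfunctions of a rectangle: separable cosine products
#' `cos(v * pi * x) * cos(w * pi * y)` with `x`, `y` normalized to
#' `[0, 1]`.
#'
#' @param v,w Mode indices (>= 0).
#' @param x,y Normalized coordinates.
#' @return Numeric vector.
#' @export
analytic_rect_mode <- function(v, w, x, y) {
  if (v < 0 || w < 0) stop_invalid("mode indices must be >= 0")
  cos(v * pi * x) * cos(w * pi * y)
}

#' Neumann eigenvalue proxy of a rectangle mode
#'
#' `(v / Lx)^2 + (w / Ly)^2`; orders the modes as the spectrum does (the
#' lowest non-constant mode varies along the longer side).
#'
#' @param v,w Mode indices.
#' @param lengths Length-2 side lengths.
#' @return Numeric scalar.
#' @export
neumann_order <- function(v, w, lengths) {
  (v / lengths[1])^2 + (w / lengths[2])^2
}

#' Shifted Legendre polynomial mode
#'
#' `P_k(2x - 1)` on `[0, 1]`, the large-bandwidth counterpart of the
#' cosine modes on latent grids.
#'
#' @param k Degree (>= 0).
#' @param x Points in `[0, 1]`.
#' @return Numeric vector.
#' @export
legendre_mode <- function(k, x) {
  if (k == 0) return(rep(1, length(x)))
  pracma::legendre(k, 2 * x - 1)[1, ]
}

#' Lissajous curve
#'
#' The planar curve `L_{p,q} = (cos(p * pi * x), cos(q * pi * x))` over
#' uniform `x` in `[0, 1]`.  `L_{1,2}` is the Chebyshev parabola
#' `y = 2 x'^2 - 1`; `L_{p,2p}` with `p > 1` are its parabolic harmonics,
#' which traverse the parabola `p` times.
#'
#' @param p,q Frequency indices.
#' @param xs Uniform parameter values in `[0, 1]`.
#' @return 2-column matrix of curve points.
#' @export
lissajous <- function(p, q, xs = seq(0, 1, length.out = 50)) {
  cbind(cos(p * pi * xs), cos(q * pi * xs))
}

#' Chebyshev polynomial of the first kind
#'
#' @param k Degree.
#' @param x Points in `[-1, 1]`.
#' @return `T_k(x)`.
#' @export
chebyshev_t <- function(k, x) cos(k * acos(pmin(1, pmax(-1, x))))
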