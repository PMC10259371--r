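#' Projection orientation as a unit quaternion
#'
#' Orientations are stored as unit quaternions in the scalar-first
#' convention `(w, x, y, z)`.  The associated rotation matrix `R` maps
#' image-frame coordinates to molecule-frame coordinates; the projection
#' integrates along the image-frame z axis, so the beam direction in the
#' molecule frame is `R %*% c(0, 0, 1)`.
#'
#' @param quaternion Length-4 numeric; must be unit norm within 1e-10
#'   unless `normalize = TRUE`.
#' @param normalize Normalize instead of erroring on non-unit input.
#' @return An object of class `orientation`.
#' @export
orientation <- function(quaternion, normalize = FALSE) {
  q <- as.numeric(quaternion)
  if (length(q) != 4) stop_invalid("quaternion must have 4 components")
  nrm <- sqrt(sum(q^2))
  if (normalize) {
    if (nrm < 1e-12) stop_invalid("zero quaternion")
    q <- q / nrm
  } else if (abs(nrm - 1) > 1e-10) {
    stop_invalid("quaternion not unit norm (|q| = %.12f)", nrm)
  }
  structure(list(q = q), class = "orientation")
}

#' @rdname orientation
#' @param axis,angle Axis (length-3) and angle in degrees for an
#'   axis-angle construction.
#' @export
orientation_axis_angle <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  h <- deg2rad(angle) / 2
  orientation(c(cos(h), sin(h) * u))
}

#' Orientation whose beam direction is a given vector
#'
#' @param beam Length-3 direction of the integration line in the molecule
#'   frame.
#' @return An `orientation` with `R %*% c(0,0,1)` parallel to `beam`.
#' @export
orientation_from_beam <- function(beam) {
  d <- beam / sqrt(sum(beam^2))
  z <- c(0, 0, 1)
  c_ <- sum(z * d)
  if (c_ > 1 - 1e-12) return(orientation(c(1, 0, 0, 0)))
  if (c_ < -1 + 1e-12) return(orientation(c(0, 1, 0, 0)))  # 180 about x
  ax <- c(z[2] * d[3] - z[3] * d[2],
          z[3] * d[1] - z[1] * d[3],
          z[1] * d[2] - z[2] * d[1])
  orientation_axis_angle(ax, rad2deg(acos(c_)))
}

#' Rotation matrix of an orientation
#'
#' @param o An `orientation`.
#' @return 3 x 3 rotation matrix.
#' @export
orientation_matrix <- function(o) {
  q <- o$q
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Beam direction of an orientation in the molecule frame
#'
#' @param o An `orientation`.
#' @return Unit length-3 vector.
#' @export
beam_direction <- function(o) as.numeric(orientation_matrix(o) %*% c(0, 0, 1))
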