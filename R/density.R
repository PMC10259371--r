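#' Rasterize an atomic structure into a 3D electron-density map
#'
#' Each atom contributes an isotropic 3D Gaussian carrying its electron
#' count.  The stated resolution is interpreted as the Gaussian FWHM, so
#' `sigma = resolution / 2.3548`.  Voxel values are the Gaussian mass
#' falling inside each voxel (per-axis differences of the normal CDF), so
#' the map integrates to the total electron count by construction.
#'
#' The grid is a `grid_size^3` cube of `voxel_size` Angstrom voxels
#' centered on the coordinate origin.
#'
#' @param structure An `atomic_structure`.
#' @param grid_size Voxels per axis (default 48).
#' @param voxel_size Angstrom per voxel (default 2).
#' @param resolution Gaussian FWHM in Angstrom (default 3).
#' @return An object of class `density_map`: `voxels` (G x G x G array),
#'   `voxel_size`, `resolution`.
#' @export
rasterize <- function(structure, grid_size = 48, voxel_size = 2,
                      resolution = 3) {
  if (resolution <= 0) stop_invalid("resolution must be positive")
  G <- as.integer(grid_size)
  sigma <- resolution / 2.3548
  half <- G * voxel_size / 2
  margin <- 3 * sigma
  ext <- max(abs(structure$coords)) + margin
  if (ext > half) {
    stop_invalid(paste0("molecule plus 3*sigma margin exceeds the box; ",
                        "need grid_size >= %d at voxel_size %.3g"),
                 ceiling(2 * ext / voxel_size), voxel_size)
  }
  # voxel boundaries along one axis (shared by all axes)
  edges <- (seq_len(G + 1) - 1 - G / 2) * voxel_size
  vox <- array(0, dim = c(G, G, G))
  win <- ceiling((4 * sigma) / voxel_size) + 1L
  for (k in seq_len(nrow(structure$coords))) {
    mu <- structure$coords[k, ]
    w <- structure$weights[k]
    ctr <- pmin(pmax(floor((mu + half) / voxel_size) + 1L, 1L), G)
    rng <- lapply(1:3, function(d) max(1L, ctr[d] - win):min(G, ctr[d] + win))
    p <- lapply(1:3, function(d) {
      e <- edges[c(rng[[d]], max(rng[[d]]) + 1L)]
      diff(stats::pnorm(e, mean = mu[d], sd = sigma))
    })
    blk <- outer(outer(p[[1]], p[[2]]), p[[3]])
    vox[rng[[1]], rng[[2]], rng[[3]]] <-
      vox[rng[[1]], rng[[2]], rng[[3]]] + w * blk
  }
  structure(list(voxels = vox, voxel_size = voxel_size,
                 resolution = resolution),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %s voxels at %.3g A/voxel, mass %.3f\n",
              paste(dim(x$voxels), collapse = "x"), x$voxel_size,
              sum(x$voxels)))
  invisible(x)
}

# voxel-center coordinate axis
.map_axis <- function(G, voxel_size) (seq_len(G) - (G + 1) / 2) * voxel_size

#' Project a density map along a viewing direction
#'
#' Parallel line integrals: the volume is resampled onto a grid rotated by
#' the orientation (trilinear interpolation) and summed along the third
#' axis.  The image value is the integral of density along the beam, so
#' total image intensity equals total map mass times `voxel_size`.
#'
#' @param map A `density_map`.
#' @param o An `orientation` (identity by default).
#' @return G x G numeric image matrix.
#' @export
project <- function(map, o = orientation(c(1, 0, 0, 0))) {
  G <- dim(map$voxels)[1]
  R <- orientation_matrix(o)
  if (max(abs(R - diag(3))) < 1e-12) {
    img <- apply(map$voxels, c(1, 2), sum) * map$voxel_size
    return(img)
  }
  ax <- .map_axis(G, map$voxel_size)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  rot <- pts %*% t(R)   # sample the map at R %*% p for image point p
  img3 <- array(trilinear_sample(map$voxels, rot, ax), dim = c(G, G, G))
  apply(img3, c(1, 2), sum) * map$voxel_size
}

# vectorized trilinear interpolation of vol at points (rows of P), axes ax
trilinear_sample <- function(vol, P, ax) {
  G <- length(ax)
  v0 <- ax[1]; dv <- ax[2] - ax[1]
  f <- sweep(P, 2, v0) / dv + 1          # fractional 1-based index
  i0 <- floor(f)
  t <- f - i0
  out <- numeric(nrow(P))
  ok <- i0[, 1] >= 1 & i0[, 1] <= G - 1 &
        i0[, 2] >= 1 & i0[, 2] <= G - 1 &
        i0[, 3] >= 1 & i0[, 3] <= G - 1
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]; t <- t[ok, , drop = FALSE]
  acc <- numeric(sum(ok))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) t[, 1] else 1 - t[, 1]) *
           (if (dy) t[, 2] else 1 - t[, 2]) *
           (if (dz) t[, 3] else 1 - t[, 3])
    idx <- (i0[, 1] + dx) + (i0[, 2] + dy - 1) * G +
           (i0[, 3] + dz - 1) * G * G
    acc <- acc + wgt * vol[idx]
  }
  out[ok] <- acc
  out
}

#' Project an atomic structure directly to an image
#'
#' Exact shortcut for the Gaussian forward model: projecting the Gaussian
#' density of an atom along the beam leaves a 2D Gaussian at the atom's
#' in-plane position, so the image can be rasterized directly from the
#' rotated coordinates with per-axis CDF differences.  Identical to
#' `project(rasterize(structure), o)` up to trilinear interpolation error,
#' and much faster for image-stack generation.
#'
#' @inheritParams rasterize
#' @param o An `orientation`.
#' @return G x G image matrix (same units as [project()]).
#' @export
project_structure <- function(structure, o = orientation(c(1, 0, 0, 0)),
                              grid_size = 48, voxel_size = 2,
                              resolution = 3) {
  G <- as.integer(grid_size)
  sigma <- resolution / 2.3548
  R <- orientation_matrix(o)
  xy <- structure$coords %*% R[, 1:2]   # in-plane coordinates t(R) %*% r
  half <- G * voxel_size / 2
  if (max(abs(xy)) + 3 * sigma > half) {
    stop_invalid("molecule exceeds the image; increase grid_size")
  }
  edges <- (seq_len(G + 1) - 1 - G / 2) * voxel_size
  img <- matrix(0, G, G)
  for (k in seq_len(nrow(xy))) {
    px <- diff(stats::pnorm(edges, xy[k, 1], sigma))
    py <- diff(stats::pnorm(edges, xy[k, 2], sigma))
    img <- img + structure$weights[k] * outer(px, py)
  }
  img * voxel_size
}

#' Contrast transfer function parameters
#'
#' @param defocus Defocus in Angstrom (positive = underfocus).
#' @param cs Spherical aberration in mm.
#' @param voltage Acceleration voltage in kV.
#' @param amplitude_contrast Amplitude-contrast fraction in `[0, 1)`.
#' @return An object of class `ctf_params`.
#' @export
ctf_params <- function(defocus = 15000, cs = 2.7, voltage = 300,
                       amplitude_contrast = 0.1) {
  if (defocus < 0) stop_invalid("defocus must be >= 0 (underfocus)")
  if (amplitude_contrast < 0 || amplitude_contrast >= 1) {
    stop_invalid("amplitude_contrast must be in [0, 1)")
  }
  structure(list(defocus = defocus, cs = cs, voltage = voltage,
                 amplitude_contrast = amplitude_contrast),
            class = "ctf_params")
}

# relativistic electron wavelength in Angstrom, voltage in kV
electron_wavelength <- function(voltage_kv) {
  V <- voltage_kv * 1e3
  12.2639 / sqrt(V + 0.97845e-6 * V^2)
}

#' Apply the contrast transfer function to an image
#'
#' Multiplies the image in the Fourier domain by
#' `CTF(k) = -(sqrt(1 - w^2) * sin(gamma) + w * cos(gamma))` with
#' `gamma(k) = pi * lambda * defocus * k^2 - (pi/2) * cs * lambda^3 * k^4`,
#' where `w` is the amplitude contrast and `k` the spatial frequency in
#' 1/Angstrom.  No envelope function or astigmatism is modeled.
#'
#' @param image Square numeric matrix.
#' @param ctf A `ctf_params`.
#' @param pixel_size Angstrom per pixel.
#' @return Real-valued filtered image of the same size.
#' @export
apply_ctf <- function(image, ctf, pixel_size) {
  G <- nrow(image)
  if (ncol(image) != G) stop_invalid("image must be square")
  if (pixel_size <= 0) stop_invalid("pixel_size must be positive")
  lambda <- electron_wavelength(ctf$voltage)
  cs_A <- ctf$cs * 1e7   # mm -> Angstrom
  fr <- c(0:(floor(G / 2)), -(ceiling(G / 2) - 1):-1)[1:G] / (G * pixel_size)
  k2 <- outer(fr^2, fr^2, "+")
  gam <- pi * lambda * ctf$defocus * k2 - (pi / 2) * cs_A * lambda^3 * k2^2
  w <- ctf$amplitude_contrast
  ctf_k <- -(sqrt(1 - w^2) * sin(gam) + w * cos(gam))
  Re(stats::fft(stats::fft(image) * ctf_k, inverse = TRUE)) / (G * G)
}

#' Add calibrated Gaussian noise to an image
#'
#' Additive zero-mean Gaussian noise with variance `var(signal) / snr`,
#' where the signal variance is computed over the molecule support (pixels
#' above 1% of the pristine image maximum).  Seeded: identical inputs give
#' bitwise-identical outputs.
#'
#' @param image Numeric matrix (the pristine image; also used for the
#'   support mask unless `reference` is given).
#' @param snr Target signal-to-noise ratio (> 0).
#' @param seed Integer seed.
#' @param reference Optional pristine reference image for variance
#'   calibration when `image` is already degraded.
#' @return Noisy image.
#' @export
add_noise <- function(image, snr, seed, reference = image) {
  if (snr <= 0) stop_invalid("snr must be positive")
  mx <- max(abs(reference))
  if (mx == 0) stop_invalid("all-zero image: SNR undefined")
  mask <- abs(reference) > 0.01 * mx
  v <- stats::var(as.numeric(reference[mask]))
  noise <- with_seed(seed, matrix(stats::rnorm(length(image),
                                               sd = sqrt(v / snr)),
                                  nrow(image)))
  image + noise
}

#' Replicate states into a projection set
#'
#' Each state appears `tau` times; replicates beyond the pristine image
#' get independent noise realizations with seeds derived deterministically
#' from `(base_seed, state, replicate)`.
#'
#' @param images List of pristine images (one per state) or a 3D array
#'   with states along the third axis.
#' @param tau Replicates per state (>= 1).
#' @param snr Target SNR, or `NULL` for pristine replicates.
#' @param base_seed Integer seed for the noise stream.
#' @param pixel_size Angstrom per pixel (metadata).
#' @return An object of class `projection_set`: `images` (G x G x N
#'   array), `meta` (data.frame with state, replicate, seed, snr),
#'   `pixel_size`.  `N = tau * M`.
#' @export
replicate_states <- function(images, tau = 1, snr = NULL, base_seed = 1,
                             pixel_size = 2) {
  if (tau < 1) stop_invalid("tau must be >= 1")
  if (is.array(images) && length(dim(images)) == 3) {
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  }
  M <- length(images)
  G <- nrow(images[[1]])
  N <- tau * M
  out <- array(0, dim = c(G, G, N))
  meta <- data.frame(state = integer(N), replicate = integer(N),
                     seed = integer(N), snr = rep(NA_real_, N))
  n <- 0L
  for (s in seq_len(M)) for (r in seq_len(tau)) {
    n <- n + 1L
    sd_ <- derive_seed(base_seed, s, r)
    img <- images[[s]]
    if (!is.null(snr)) img <- add_noise(img, snr, sd_)
    out[, , n] <- img
    meta$state[n] <- s; meta$replicate[n] <- r; meta$seed[n] <- sd_
    meta$snr[n] <- if (is.null(snr)) NA_real_ else snr
  }
  structure(list(images = out, meta = meta, pixel_size = pixel_size),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("projection_set: %d images of %dx%d pixels\n",
              dim(x$images)[3], dim(x$images)[1], dim(x$images)[2]))
  invisible(x)
}

#' Choose the five canonical projection directions
#'
#' PD_1 views along the first hinge axis, so the first motion happens
#' entirely in the image plane; PD_2 (when a second hinge exists) views
#' along the second hinge axis.  Three further directions are drawn
#' deterministically from a seeded uniform distribution on the sphere,
#' rejecting directions within 5 degrees of any already chosen.
#'
#' @param ensemble A `conformer_ensemble` (>= 1 hinge).
#' @param seed Integer seed for the arbitrary directions.
#' @param n_total Total number of directions (default 5).
#' @return List of `n_total` `orientation` objects.
#' @export
choose_pds <- function(ensemble, seed = 1, n_total = 5) {
  hinges <- ensemble$hinges
  if (length(hinges) < 1) stop_invalid("ensemble has no hinges")
  beams <- list(hinges[[1]]$axis)
  if (length(hinges) > 1) beams <- c(beams, list(hinges[[2]]$axis))
  sep_ok <- function(d, ds) {
    all(vapply(ds, function(e) {
      acos(pmin(1, abs(sum(d * e)))) > deg2rad(5)
    }, logical(1)))
  }
  target <- n_total
  with_seed(seed, {
    while (length(beams) < target) {
      z <- stats::runif(1, -1, 1)
      phi <- stats::runif(1, 0, 2 * pi)
      d <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
      if (sep_ok(d, beams)) beams <- c(beams, list(d))
    }
  })
  lapply(beams, orientation_from_beam)
}
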