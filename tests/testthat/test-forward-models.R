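test_that("rasterization conserves each atom's electron count", {
  s1 <- atomic_structure(matrix(c(1.3, -2.1, 0.7), 1), weights = 1)
  m1 <- rasterize(s1, grid_size = 32, voxel_size = 2, resolution = 3)
  expect_equal(sum(m1$voxels), 1, tolerance = 1e-3)
  expect_true(all(m1$voxels >= 0))
  # map is maximal at the atom position for an isolated atom
  peak <- which(m1$voxels == max(m1$voxels), arr.ind = TRUE)[1, ]
  ax <- (seq_len(32) - 16.5) * 2
  expect_lt(max(abs(c(ax[peak[1]], ax[peak[2]], ax[peak[3]]) -
                    s1$coords[1, ])), 2)
  mol <- toy_mol()
  mm <- rasterize(mol)
  expect_equal(sum(mm$voxels), sum(mol$weights), tolerance = 1e-3 *
                 sum(mol$weights))
  expect_error(rasterize(atomic_structure(matrix(c(80, 0, 0), 1)),
                         grid_size = 32), "grid_size")
})

test_that("rasterize and project are linear in atom weights", {
  a <- atomic_structure(matrix(c(3, 1, -2), 1), weights = 2)
  b <- atomic_structure(matrix(c(-4, 2, 5), 1), weights = 5)
  ab <- atomic_structure(rbind(a$coords, b$coords), weights = c(2, 5))
  ma <- rasterize(a, 32); mb <- rasterize(b, 32); mab <- rasterize(ab, 32)
  expect_lt(max(abs(mab$voxels - ma$voxels - mb$voxels)), 1e-12)
  o <- orientation_axis_angle(c(1, 2, 0), 40)
  expect_lt(max(abs(project(mab, o) - project(ma, o) - project(mb, o))),
            1e-10)
})

test_that("the 1D profile FWHM equals the stated resolution within a voxel", {
  s <- atomic_structure(matrix(0, 1, 3), weights = 1)
  res <- 3
  m <- rasterize(s, grid_size = 48, voxel_size = 1, resolution = res)
  prof <- m$voxels[, 25, 25]
  ax <- (seq_len(48) - 24.5) * 1
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  # linear interpolation at the half-maximum crossings
  lo <- ax[above[1] - 1] + (half - prof[above[1] - 1]) /
    (prof[above[1]] - prof[above[1] - 1])
  hi <- ax[above[2]] + (prof[above[2]] - half) /
    (prof[above[2]] - prof[above[2] + 1])
  expect_lt(abs((hi - lo) - res), 1)
})

test_that("projection conserves mass for arbitrary orientations", {
  # adequately sampled map: voxel size below the Gaussian sigma
  mm <- fixture("toy_map_fine",
                function() rasterize(toy_mol(), 56, 1.5, 6))
  total <- sum(mm$voxels) * mm$voxel_size
  img0 <- project(mm)
  expect_equal(img0, apply(mm$voxels, c(1, 2), sum) * mm$voxel_size)
  set.seed(7)
  for (i in 1:20) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    o <- orientation_axis_angle(u, stats::runif(1, 0, 360))
    expect_lt(abs(sum(project(mm, o)) - total) / total, 1e-3)
  }
})

test_that("projecting an isotropic Gaussian keeps its width", {
  # analytic marginalization: a 3D Gaussian of width sigma projects to a
  # 2D Gaussian of the same sigma
  s <- atomic_structure(matrix(0, 1, 3), weights = 1)
  res <- 6   # sigma = 2.548 A
  sigma <- res / 2.3548
  m <- rasterize(s, 48, 1, res)
  o <- orientation_axis_angle(c(1, 1, 1), 70)
  img <- project(m, o)
  ax <- (seq_len(48) - 24.5)
  # least-squares fit of log intensity against quadratic radius
  w <- which(img > max(img) * 1e-3, arr.ind = TRUE)
  r2 <- ax[w[, 1]]^2 + ax[w[, 2]]^2
  fit <- stats::lm(log(img[w]) ~ r2)
  sigma_fit <- sqrt(-1 / (2 * coef(fit)[2]))
  expect_equal(unname(sigma_fit), sigma, tolerance = 0.05)
})

test_that("structure-space projection matches map-space projection", {
  mol <- toy_mol()
  o <- orientation_axis_angle(c(0, 1, 1), 55)
  img_map <- project(fixture("toy_map_fine",
                             function() rasterize(toy_mol(), 56, 1.5,
                                                  6)), o)
  img_str <- project_structure(mol, o, 56, 1.5, 6)
  # identical up to trilinear interpolation error of the map route
  expect_lt(max(abs(img_map - img_str)) / max(img_str), 0.05)
  expect_equal(sum(img_map), sum(img_str), tolerance = 1e-3 * sum(img_str))
})

test_that("foreshortening scales in-plane displacement by the cosine", {
  # a single atom displaced in 3D appears displaced by the projection of
  # that displacement onto the image plane; measured via the intensity
  # centroid, which for a Gaussian spot is its center
  centroid <- function(img) {
    ax <- (seq_len(nrow(img)) - (nrow(img) + 1) / 2) * 2
    c(sum(ax * rowSums(img)), sum(ax * colSums(img))) / sum(img)
  }
  delta <- c(6, 0, 3)          # 3D displacement
  s0 <- atomic_structure(matrix(c(-3, 0, -1.5), 1), weights = 1)
  s1 <- atomic_structure(s0$coords + rep(delta, each = 1), weights = 1)
  for (ang in c(0, 30, 60)) {
    o <- orientation_axis_angle(c(0, 1, 0), ang)
    R <- orientation_matrix(o)
    inplane <- sqrt(sum((t(R[, 1:2]) %*% delta)^2))
    c0 <- centroid(project_structure(s0, o, 32, 2, 3))
    c1 <- centroid(project_structure(s1, o, 32, 2, 3))
    expect_lt(abs(sqrt(sum((c1 - c0)^2)) - inplane), 0.5 * 2)
  }
})

test_that("CTF is multiplicative, real, and kills DC when w = 0", {
  mol <- toy_mol()
  img <- project_structure(mol, grid_size = 48)
  ctf <- ctf_params(defocus = 15000, cs = 2.7, voltage = 300,
                    amplitude_contrast = 0.1)
  once <- apply_ctf(img, ctf, 2)
  twice <- apply_ctf(once, ctf, 2)
  # independent route: one multiplication by CTF^2 in Fourier space
  G <- 48
  fr <- c(0:(G / 2), -(G / 2 - 1):-1)[1:G] / (G * 2)
  k2 <- outer(fr^2, fr^2, "+")
  lambda <- manifoldlab:::electron_wavelength(300)
  gam <- pi * lambda * 15000 * k2 - (pi / 2) * 2.7e7 * lambda^3 * k2^2
  w <- 0.1
  ck <- -(sqrt(1 - w^2) * sin(gam) + w * cos(gam))
  direct <- Re(stats::fft(stats::fft(img) * ck^2, inverse = TRUE)) / G^2
  expect_lt(max(abs(twice - direct)), 1e-10 * max(abs(img)))
  expect_true(is.numeric(once) && all(is.finite(once)))
  # zero amplitude contrast: gamma(0) = 0 so the DC term vanishes
  ctf0 <- ctf_params(amplitude_contrast = 0)
  filt <- apply_ctf(img, ctf0, 2)
  expect_lt(abs(sum(filt)), 1e-8 * sum(img))
  expect_error(ctf_params(amplitude_contrast = 1), "amplitude_contrast")
})

test_that("noise is seeded, calibrated, and measurable at the stated SNR", {
  big <- atomic_structure(
    as.matrix(expand.grid(seq(-40, 40, by = 4), seq(-40, 40, by = 4), 0)),
    weights = 6)
  img <- project_structure(big, grid_size = 128, voxel_size = 1)
  n1 <- add_noise(img, snr = 0.5, seed = 42)
  n2 <- add_noise(img, snr = 0.5, seed = 42)
  expect_identical(n1, n2)
  expect_false(identical(n1, add_noise(img, snr = 0.5, seed = 43)))
  # re-estimate both variances on the generated image
  mask <- abs(img) > 0.01 * max(abs(img))
  v_sig <- stats::var(img[mask])
  v_noise <- stats::var((n1 - img)[!mask])
  expect_lt(abs(v_sig / v_noise - 0.5) / 0.5, 0.10)
  expect_error(add_noise(matrix(0, 8, 8), 1, 1), "all-zero")
})

test_that("replicate_states produces tau sightings per state", {
  imgs <- lapply(1:4, function(i) outer(1:8, 1:8) * i / 8)
  ps0 <- replicate_states(imgs, tau = 1, snr = NULL, base_seed = 1)
  expect_equal(dim(ps0$images)[3], 4)
  expect_equal(ps0$images[, , 3], imgs[[3]])
  ps <- replicate_states(imgs, tau = 5, snr = 2, base_seed = 1)
  expect_equal(dim(ps$images)[3], 20)
  expect_equal(ps$meta$state, rep(1:4, each = 5))
  # replicates of one state differ only by a zero-mean noise field
  d <- ps$images[, , 1] - ps$images[, , 2]
  expect_lt(abs(mean(d)), 4 * stats::sd(d) / 8)
  expect_gt(stats::sd(d), 0)
  # tau = 5 on 400 states gives 2000 images
  imgs400 <- lapply(1:400, function(i) matrix(i * 1.0, 2, 2))
  expect_equal(dim(replicate_states(imgs400, tau = 5, snr = 1,
                                    base_seed = 2)$images)[3], 2000)
})

test_that("choose_pds returns five distinct, seed-stable directions", {
  ens <- toy_ss2_small()
  pds <- choose_pds(ens, seed = 11)
  expect_length(pds, 5)
  # PD_1 looks along the first hinge axis
  expect_equal(abs(sum(beam_direction(pds[[1]]) * ens$hinges[[1]]$axis)),
               1, tolerance = 1e-10)
  expect_equal(abs(sum(beam_direction(pds[[2]]) * ens$hinges[[2]]$axis)),
               1, tolerance = 1e-10)
  dirs <- vapply(pds, beam_direction, numeric(3))
  for (i in 1:4) for (j in (i + 1):5) {
    ang <- acos(min(1, abs(sum(dirs[, i] * dirs[, j])))) * 180 / pi
    expect_gt(ang, 5)
  }
  pds2 <- choose_pds(ens, seed = 11)
  expect_identical(lapply(pds, `[[`, "q"), lapply(pds2, `[[`, "q"))
  # quaternions are unit scalar-first
  expect_equal(vapply(pds, function(o) sum(o$q^2), numeric(1)), rep(1, 5))
})

test_that("MRC volumes and stacks round-trip at float32", {
  m <- rasterize(toy_mol(), 24, 4, 6)
  tmp <- tempfile(fileext = ".mrc")
  write_mrc(m, tmp)
  back <- read_mrc(tmp)
  expect_equal(back$voxel_size, 4)
  expect_false(back$is_stack)
  expect_identical(back$data,
                   array(readBin(writeBin(as.numeric(m$voxels), raw(),
                                          size = 4),
                                 "numeric", length(m$voxels), size = 4),
                         dim = dim(m$voxels)))
  imgs <- lapply(1:3, function(i) matrix(stats::rnorm(64), 8, 8))
  ps <- replicate_states(imgs, tau = 1, base_seed = 1, pixel_size = 1.5)
  tmp2 <- tempfile(fileext = ".mrc")
  write_mrc(ps, tmp2)
  back2 <- read_mrc(tmp2)
  expect_true(back2$is_stack)
  expect_equal(dim(back2$data)[3], 3)
  expect_equal(back2$voxel_size, 1.5)
})
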