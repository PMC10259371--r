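test_that("analytic interval and rectangle modes have the canonical form", {
  x <- seq(0, 1, length.out = 101)
  expect_equal(analytic_interval_mode(0, x), rep(1, 101))
  expect_equal(analytic_interval_mode(1, c(0, 0.5, 1)), c(1, 0, -1))
  # orthogonality under trapezoid weights on equispaced x
  wts <- c(0.5, rep(1, 99), 0.5)
  for (k in 1:4) for (kp in 1:4) {
    ip <- sum(wts * analytic_interval_mode(k, x) *
                analytic_interval_mode(kp, x)) / 100
    expect_equal(ip, if (k == kp) 0.5 else 0, tolerance = 1e-10)
  }
  y <- rev(x)
  expect_equal(analytic_rect_mode(0, 0, x, y), rep(1, 101))
  expect_equal(analytic_rect_mode(2, 3, x, y),
               analytic_rect_mode(2, 0, x, y) *
                 analytic_rect_mode(0, 3, x, y))
  # on [0,1] x [0,1.1] the lowest nonconstant mode varies along the
  # longer side
  expect_lt(neumann_order(0, 1, c(1, 1.1)), neumann_order(1, 0, c(1, 1.1)))
})

test_that("L_{1,2} is the Chebyshev parabola with nonuniform spacing", {
  xs <- seq(0, 1, length.out = 50)
  L <- lissajous(1, 2, xs)
  expect_equal(L[, 2], 2 * L[, 1]^2 - 1, tolerance = 1e-14)
  expect_equal(L[, 2], chebyshev_t(2, L[, 1]), tolerance = 1e-12)
  np <- nonuniformity_profile(L)
  expect_gt(np$ratio, 1.5)
  # uniform points on a line have ratio 1, invariant under scaling
  line <- cbind(xs, xs)
  expect_equal(nonuniformity_profile(line)$ratio, 1, tolerance = 1e-10)
  expect_equal(nonuniformity_profile(100 * L)$ratio, np$ratio,
               tolerance = 1e-12)
  # degenerate Lissajous with p = q lies on the identity line
  L11 <- lissajous(1, 1, xs)
  expect_equal(L11[, 1], L11[, 2])
})

test_that("parabolic-harmonic multiplicity counts monotone segments", {
  xs <- seq(0, 1, length.out = 60)
  expect_equal(harmonic_multiplicity(lissajous(1, 2, xs)), 1L)
  expect_equal(harmonic_multiplicity(lissajous(2, 4, xs)), 2L)
  expect_equal(harmonic_multiplicity(lissajous(3, 6, xs)), 3L)
  expect_error(harmonic_multiplicity(lissajous(1, 2, c(0, 1))), "3 points")
  # brute-force preimage oracle: bin the parabola's locus (monotone in
  # the first coordinate) into 50 bins and count maximal runs of
  # consecutive parameter indices landing in each bin; the largest run
  # count over interior bins is the number of traversals
  brute_mult <- function(L) {
    bins <- cut(L[, 1], breaks = seq(min(L[, 1]), max(L[, 1]),
                                     length.out = 51),
                include.lowest = TRUE)
    runs_per_bin <- tapply(seq_len(nrow(L)), bins, function(idx) {
      if (!length(idx)) return(0L)
      sum(diff(idx) > 1) + 1L
    })
    max(unlist(runs_per_bin), na.rm = TRUE)
  }
  for (p in 1:4) {
    L <- lissajous(p, 2 * p, seq(0, 1, length.out = 200))
    expect_equal(harmonic_multiplicity(L), brute_mult(L),
                 info = paste("p =", p))
  }
})

test_that("mode assignment recovers planted modes exactly", {
  g <- make_latent_grid(2, c(21, 21), c(1, 1.1))
  ord <- ground_truth_ordering(g)
  x <- ord[[1]]$x; y <- ord[[2]]$x
  planted <- list(c(1, 0), c(0, 1), c(2, 1), c(1, 1), c(0, 3))
  V <- vapply(planted, function(vw) {
    cos(vw[1] * pi * x) * cos(vw[2] * pi * y)
  }, numeric(length(x)))
  emb <- structure(list(values = c(1, seq(0.9, by = -0.1,
                                          length.out = 5)),
                        vectors = cbind(1, V), method = "DM",
                        epsilon = 1, alpha = 1, k = 5),
                   class = "embedding")
  asg <- assign_modes(emb, ord, max_mode = 3)
  for (i in seq_along(planted)) {
    expect_equal(c(asg$v[i], asg$w[i]), planted[[i]])
    expect_equal(asg$r[i], 1, tolerance = 1e-12)
  }
  expect_equal(asg$class[1], "pure-CM")
  expect_equal(asg$class[3], "cross-term")
  # an equal admixture is labeled mixed, never forced to a pure mode
  mix <- (cos(pi * x) + cos(pi * y)) / sqrt(2)
  emb$vectors[, 2] <- mix
  asg2 <- assign_modes(emb, ord, max_mode = 3)
  expect_true(asg2$class[1] %in% c("mixed", "unclassified"))
  expect_lt(asg2$r[1], 0.9)
  expect_error(assign_modes(emb, ground_truth_ordering(
    make_latent_grid(2, c(5, 5), c(1, 1)))), "mismatch")
})

test_that("degenerate pairs are flagged by spectral gap", {
  expect_equal(nrow(detect_degenerate_pairs(c(0.9, 0.9, 0.5), 1e-6)), 1)
  expect_equal(detect_degenerate_pairs(c(0.9, 0.9, 0.5), 1e-6)[1, ],
               c(i = 1, j = 2))
  expect_equal(nrow(detect_degenerate_pairs(c(0.9, 0.6, 0.3), 1e-3)), 0)
})

test_that("rotation recovery finds planted admixture angles", {
  x <- seq(0, 1, length.out = 30)
  g <- expand.grid(x = x, y = x)
  t1 <- cos(pi * g$x); t2 <- cos(pi * g$y)
  targets <- cbind(t1, t2)
  # identity input
  rec0 <- recover_rotation(targets, targets)
  expect_lt(dist_mod90(rec0$theta, 0), 1)
  # explicit 45-degree admixture
  V45 <- rotate_pair(targets, 45)
  rec45 <- recover_rotation(V45, targets)
  expect_lt(dist_mod90(rec45$theta, 45), 1)
  expect_true(rec45$success)
  expect_equal(sum(rec45$beta^2), 1, tolerance = 1e-12)

  # 100 planted angles: noise-free recovery to 1 degree, median 0.5
  set.seed(9)
  thetas <- stats::runif(100, 0, 90)
  err <- vapply(thetas, function(th) {
    V <- rotate_pair(targets, th)
    rec <- recover_rotation(V, targets)
    dist_mod90(rec$theta, (90 - th) %% 90)
  }, numeric(1))
  expect_lte(stats::median(err), 0.5)
  expect_lte(max(err), 1)

  # with 5% RMS additive vector noise, recovery within 3 degrees
  err_n <- vapply(thetas, function(th) {
    V <- rotate_pair(targets, th)
    V <- V + matrix(stats::rnorm(length(V),
                                 sd = 0.05 * sqrt(mean(V^2))),
                    nrow(V))
    rec <- recover_rotation(V, targets)
    dist_mod90(rec$theta, (90 - th) %% 90)
  }, numeric(1))
  expect_lte(max(err_n), 3)
})

test_that("successive decoupling angles are 90 degrees apart", {
  x <- seq(0, 1, length.out = 25)
  g <- expand.grid(x = x, y = x)
  targets <- cbind(cos(pi * g$x), cos(pi * g$y))
  V <- rotate_pair(targets, 28.25)
  sc <- rotation_scan(V, targets)
  expect_gte(length(sc$peaks), 4)
  expect_true(all(abs(sc$spacings - 90) <= 1))
})

test_that("subspace classification labels the T2 parabola per CM", {
  # synthetic embedding from pure interval modes k = 1..4
  x <- seq(0, 1, length.out = 40)
  V <- vapply(1:4, function(k) cos(k * pi * x), numeric(40))
  emb <- structure(list(values = c(1, 0.8, 0.6, 0.4, 0.2),
                        vectors = cbind(1, V), method = "DM",
                        epsilon = 1, alpha = 1, k = 4),
                   class = "embedding")
  g <- make_latent_grid(1, 40, 1)
  ord <- ground_truth_ordering(g)
  curves <- classify_subspaces(emb, ord, max_freq = 5)
  p12 <- curves[curves$i == 1 & curves$j == 2, ]
  expect_equal(nrow(p12), 1)
  expect_equal(c(p12$p, p12$q), c(1, 2))
  expect_equal(p12$chebyshev, "T2")
  expect_true(p12$monotonic)
  expect_lt(p12$t2_residual, 0.05)
  # deeper partner pairs are harmonic, not monotonic
  p24 <- curves[curves$j == 4 & curves$q == 4, ]
  expect_true(all(!is.na(p24$multiplicity)))
})

test_that("SS2 latent embedding holds one leading monotone parabola per CM", {
  g <- make_latent_grid(2, c(20, 20), c(1, 1.1))
  D <- euclidean_distance_matrix(g)
  ord <- ground_truth_ordering(g)
  emb <- diffusion_map(D, eps_regime(D, "small"), k = 12)
  curves <- classify_subspaces(emb, ord, max_pairs = 10)
  for (cm in 1:2) {
    lead <- curves[curves$cm == cm & curves$chebyshev == "T2" &
                     curves$monotonic & !is.na(curves$chebyshev), ]
    expect_gte(nrow(lead), 1)
    expect_lt(min(lead$t2_residual), 0.05)
  }
})
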