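test_that("spline smoothing reproduces polynomials and damps noise", {
  wl <- seq(400, 900, by = 5)
  expect_equal(smooth_curve(rep(0.3, 101), wl), rep(0.3, 101),
               tolerance = 1e-9)
  ramp <- seq(0.1, 0.9, length.out = 101)
  expect_equal(smooth_curve(ramp, wl), ramp, tolerance = 1e-9)

  set.seed(4)
  clean <- sin(seq(0, 3 * pi, length.out = 101)) * 0.3 + 0.5
  noisy <- clean + rnorm(101, 0, 0.02)
  sm <- smooth_curve(noisy, wl)
  expect_lt(sqrt(mean((sm - noisy)^2)), 0.02)
  tv <- function(x) sum(abs(diff(x)))
  expect_lt(tv(sm), tv(noisy))

  expect_error(smooth_curve(c(noisy[-1], NA), wl), "non-finite")
  expect_error(smooth_curve(1:5, (1:5) * 100), "at least 10")
})

test_that("region PCA matches a brute-force eigendecomposition", {
  set.seed(3)
  X <- matrix(rnorm(200 * 5), 200, 5) %*% matrix(rnorm(25), 5)
  wl <- c(450, 500, 550, 600, 650)
  p <- pca_region(X, c(450, 650), wl)

  S <- cov(sweep(X, 2, colMeans(X)))
  e <- eigen(S, symmetric = TRUE)
  expect_lt(max(abs(p$eigenvalues - e$values)), 1e-8)
  # sign-aligned loadings
  for (i in 1:5) {
    v <- e$vectors[, i] * sign(sum(e$vectors[, i] * p$loadings[, i]))
    expect_lt(max(abs(v - p$loadings[, i])), 1e-8)
  }
  expect_lt(abs(sum(p$eigenvalues) - sum(diag(S))),
            1e-6 * sum(diag(S)))
  expect_lt(max(abs(crossprod(p$loadings) - diag(5))), 1e-6)
  # scores are the centered data in the loading basis
  expect_lt(max(abs(p$scores %*% t(p$loadings) + rep(1, 200) %o% p$center
                    - X)), 1e-8)
})

test_that("PCA handles degenerate and restricted cases", {
  # two perfectly correlated bands
  X2 <- cbind(c(1, 2, 3), c(1, 2, 3))
  p2 <- pca_region(X2, c(400, 900), c(500, 600))
  expect_equal(p2$eigenvalues, c(2 * var(c(1, 2, 3)), 0))
  expect_equal(abs(p2$loadings[, 1]), c(1, 1) / sqrt(2))

  # 450-850 restriction of the default grid keeps 81 bands
  set.seed(5)
  X <- matrix(runif(120 * 101), 120, 101)
  p <- pca_region(X, c(450, 850))
  expect_equal(length(p$wavelengths), 81)
  expect_equal(nrow(p$loadings), 81)

  expect_error(pca_region(X[1:50, ], c(450, 850)), "rank-deficient")

  # scale equivariance: eigenvalues scale by c^2, loadings fixed up to sign
  Xs <- matrix(rnorm(80 * 6), 80, 6)
  pa <- pca_region(Xs, c(400, 900), seq(400, 650, 50))
  pb <- pca_region(3 * Xs, c(400, 900), seq(400, 650, 50))
  expect_equal(pb$eigenvalues, 9 * pa$eigenvalues, tolerance = 1e-8)
  expect_lt(max(abs(abs(pb$loadings) - abs(pa$loadings))), 1e-8)
})

test_that("weight curves scale loadings by their eigenvalue", {
  set.seed(6)
  X <- matrix(rnorm(100 * 8), 100, 8)
  p <- pca_region(X, c(400, 900), seq(400, 750, 50))
  g1 <- weight_curve(p, 1)
  expect_equal(g1, p$eigenvalues[1] * p$loadings[, 1])
  # zero-eigenvalue component has an identically zero curve
  Xdep <- cbind(X[, 1:3], X[, 1] + X[, 2])
  pd <- pca_region(Xdep, c(400, 900), c(400, 450, 500, 550))
  expect_equal(weight_curve(pd, 4), rep(0, 4), tolerance = 1e-10)
  # positive scaling preserves the argmax of |gamma|
  expect_equal(which.max(abs(g1)), which.max(abs(p$loadings[, 1])))
  expect_error(weight_curve(p, 9), "retained")
})

test_that("wavelength selection picks separated extrema", {
  wl <- seq(450, 850, by = 5)
  g <- -0.5 * exp(-((wl - 500) / 25)^2) + 0.4 * exp(-((wl - 650) / 25)^2) -
    0.3 * exp(-((wl - 800) / 25)^2) + 0.001 * (wl - 650) / 200
  # brute-force extrema check: the three Gaussian centers dominate
  expect_equal(select_wavelengths(g, wl), c(500, 650, 800))
  # monotone curve has only the two endpoints as candidates
  expect_error(select_wavelengths(seq(0, 1, length.out = 81), wl),
               "insufficient extrema")
  # separation constraint suppresses a nearby second peak
  g2 <- -0.5 * exp(-((wl - 500) / 20)^2) + 0.45 * exp(-((wl - 540) / 15)^2) +
    0.3 * exp(-((wl - 700) / 25)^2) - 0.2 * exp(-((wl - 820) / 20)^2)
  sel <- select_wavelengths(g2, wl, k = 3, min_sep = 80)
  expect_true(all(diff(sort(sel)) >= 80))
})

test_that("band selection is stable across generator seeds", {
  triples <- NULL
  for (s in c(0, 11, 22, 33, 44, 55)) {
    scenes <- lapply(s * 7 + (1:6), function(k)
      render_scene(scene_config(height = 96, width = 96, n_leaves = 8,
                                seed = k, n_ntrms_per_class = c(1, 1, 1))))
    triples <- rbind(triples, select_bands(scenes, pc_index = 1)$bands)
  }
  expect_equal(nrow(unique(triples)), 1)
  # the selected triple is widely separated, inside the region
  expect_true(all(diff(triples[1, ]) >= 80))
  expect_true(all(triples[1, ] >= 450 & triples[1, ] <= 850))
})
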