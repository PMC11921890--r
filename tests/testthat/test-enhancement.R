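test_that("pseudo-color composition maps bands by descending wavelength", {
  sc <- fixture_scenes()[[1]]
  pcc <- pseudo_color(sc$cube, c(580, 680, 850))
  expect_equal(pcc$band_map, c(850, 680, 580))
  expect_equal(unname(apply(pcc$pixels, 3, max)), c(255, 255, 255))
  expect_equal(unname(apply(pcc$pixels, 3, min)), c(0, 0, 0))
  expect_error(pseudo_color(sc$cube, c(580, 580, 850)), "duplicate")

  # constant band maps to a zero channel
  flat <- spectral_cube(array(rep(seq(0.1, 0.9, length.out = 101),
                                  each = 16), c(4, 4, 101)))
  p2 <- pseudo_color(flat, c(500, 600, 700))
  expect_true(all(p2$pixels == 0))
})

test_that("decorrelation stretch whitens channel correlations", {
  set.seed(8)
  for (rep in 1:5) {
    # strongly correlated random channels
    base <- matrix(rnorm(1200), 400, 3)
    A <- matrix(rnorm(9, sd = 1), 3) + diag(3)
    X <- pmin(pmax(128 + base %*% A * 30, 0), 255)
    img <- array(X, c(20, 20, 3))
    d <- decorrelation_stretch(img)
    cc <- cor(d$stretch_params$pre_clip)
    expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
    # each pre-clip channel is rescaled to the target SD
    expect_equal(unname(apply(d$stretch_params$pre_clip, 2, sd)),
                 rep(60, 3), tolerance = 1e-4)  # ridge shrinks marginally
  }
})

test_that("stretch of already-white data is the identity up to rounding", {
  set.seed(9)
  M <- scale(matrix(rnorm(400 * 3), 400, 3), scale = FALSE)
  Q <- qr.Q(qr(M))              # mean-zero, exactly uncorrelated columns
  X <- 128 + Q * 30 * sqrt(399) # per-channel SD exactly 30
  img <- array(X, c(20, 20, 3))
  d <- decorrelation_stretch(img, target_sd = 30)
  expect_lte(max(abs(d$pixels - img)), 1)
})

test_that("stretch handles degenerate covariance via the ridge", {
  img <- array(0.5, c(8, 8, 3))
  expect_error(decorrelation_stretch(img), "degenerate covariance")
  set.seed(10)
  img2 <- array(runif(8 * 8 * 3) * 255, c(8, 8, 3))
  img2[, , 2] <- img2[, , 1]  # rank-deficient without the ridge
  d <- decorrelation_stretch(img2)
  expect_true(all(is.finite(d$pixels)))
})

test_that("pre-clip correlations are invariant to channel-wise affine input", {
  set.seed(11)
  base <- matrix(rnorm(900), 300, 3)
  A <- matrix(c(1, .8, .6, .8, 1, .7, .6, .7, 1), 3)
  X <- 100 + base %*% chol(A) * 20
  img <- array(X, c(15, 20, 3))
  img2 <- img
  img2[, , 1] <- img2[, , 1] * 1.7 + 30
  img2[, , 3] <- img2[, , 3] * 0.5 - 10
  c1 <- cor(decorrelation_stretch(img)$stretch_params$pre_clip)
  c2 <- cor(decorrelation_stretch(img2)$stretch_params$pre_clip)
  expect_lt(max(abs(c1 - c2)), 1e-5)
})

test_that("DCS separates object classes more than PCC on scenes", {
  wins <- 0
  scenes <- fixture_scenes(4)
  for (sc in scenes) {
    pcc <- pseudo_color(sc$cube, c(550, 670, 850))
    dcs <- decorrelation_stretch(pcc)
    sep_p <- class_color_separation(pcc$pixels, sc$material_map)
    sep_d <- class_color_separation(dcs$pixels, sc$material_map)
    wins <- wins + (sep_d > sep_p)
  }
  expect_gte(wins, 3)
})
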