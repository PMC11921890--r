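ns <- asNamespace("dbytk")

test_that("channel shuffle follows the interleaving definition", {
  # 6 channels, 2 groups: (0,1,2,3,4,5) -> (0,3,1,4,2,5)
  expect_equal(ns$shuffle_perm(6, 2) - 1L, c(0, 3, 1, 4, 2, 5))
  expect_equal(ns$shuffle_perm(9, 3) - 1L, c(0, 3, 6, 1, 4, 7, 2, 5, 8))
})

test_that("MBModule preserves shape and enforces divisibility", {
  set.seed(2)
  mb <- ns$mk_mb(27, c(3, 5, 7), 3)
  x <- array(rnorm(12 * 10 * 27 * 2), c(12, 10, 27, 2))
  y <- ns$m_fwd(mb, x, TRUE)
  expect_equal(dim(y), dim(x))
  expect_error(ns$mk_mb(10, c(3, 5, 7), 3), "divisible by 3\\*groups")

  # a depthwise k x k over C channels holds C*k^2 weights
  expect_length(ns$mk_dwconv(16, 5)$W, 16 * 25)
  # Conv(3->16, k=3, BN) holds 3*16*9 + 2*16 = 464 parameters
  cv <- ns$mk_conv(3, 16, 3)
  expect_equal(sum(lengths(lapply(cv$pnames, function(p) cv[[p]]))), 464)
})

test_that("C2f_EL output matches shape and receives gradient everywhere", {
  set.seed(3)
  m <- ns$mk_c2fel(12, 12, 9, 1, c(3, 5, 7), 3)
  x <- array(rnorm(8 * 8 * 12), c(8, 8, 12, 1))
  y <- ns$m_fwd(m, x, TRUE)
  expect_equal(dim(y)[1:2], dim(x)[1:2])
  ns$m_bwd(m, array(rnorm(length(y)), dim(y)))
  mods <- list()
  ns$walk_mods(m, function(z) mods[[length(mods) + 1]] <<- z)
  for (mm in mods)
    for (p in mm$pnames) {
      g <- mm[[paste0("d", p)]]
      expect_false(is.null(g))
      expect_gt(max(abs(g)), 0)  # every branch's kernel sees gradient
    }
})

test_that("detector outputs three scales with stride-8/16/32 geometry", {
  sp <- model_spec(widths = c(6, 12, 12, 24, 48),
                   neck_hidden = c(n3 = 9, td4 = 9, n4 = 9, n5 = 9))
  m <- build_model(sp, seed = 1)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  outs <- net_forward(m, list(rgb = x, dcs = x))
  expect_equal(vapply(outs, function(o) dim(o$cls)[1], 0), c(8, 4, 2))
  expect_equal(vapply(outs, function(o) dim(o$box)[3], 0), rep(64, 3))
  expect_equal(vapply(outs, function(o) dim(o$cls)[3], 0), rep(3, 3))
  expect_error(net_forward(m, list(rgb = x[1:60, , , , drop = FALSE],
                                   dcs = x[1:60, , , , drop = FALSE])),
               "divisible by 32")
  # evaluation-mode forward is deterministic
  o1 <- net_forward(m, list(rgb = x, dcs = x))
  o2 <- net_forward(m, list(rgb = x, dcs = x))
  expect_identical(o1, o2)
})

test_that("loss formulas match their closed forms", {
  # BCE in base 2: q=1, p=0.5 -> 1 bit
  expect_equal(loss_bce(0.5, 1, log_base = "2"), 1)
  expect_equal(loss_bce(0.5, 1), log(2))
  # clamping keeps exact 0/1 probabilities finite
  expect_true(is.finite(loss_bce(1, 0)))
  # CIoU of a box against itself is zero
  b <- c(10, 20, 50, 60)
  expect_equal(loss_ciou(b, b), 0, tolerance = 1e-9)
  expect_equal(ciou(b, b), 1, tolerance = 1e-9)
  # disjoint boxes: IoU term zero, distance term positive
  expect_gt(loss_ciou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 1)
  # DFL: target exactly on a bin with all mass there is zero
  expect_equal(loss_dfl(1, 0, y = 3, y_i = 3, y_ip1 = 4), 0)
  expect_equal(loss_dfl(0.5, 0.5, y = 3.5, y_i = 3, y_ip1 = 4,
                        log_base = "2"), 1)
  # weighted sum
  expect_equal(total_loss(1, 2, 3), 7.5 + 1 + 4.5)
  expect_equal(total_loss(0, 0, 0), 0)
})

test_that("fusion weights stay effectively non-negative through training", {
  sp <- model_spec(widths = c(6, 12, 12, 24, 48),
                   neck_hidden = c(n3 = 9, td4 = 9, n4 = 9, n5 = 9))
  m <- build_model(sp, seed = 5)
  scenes <- easy_scenes(25)[1:3]
  train_detector(m, scenes, n_iter = 12, batch_size = 2, lr = 0.05,
                 seed = 1)
  for (nm in c("fu_td4", "fu_n3", "fu_n4", "fu_n5")) {
    fu <- m$neck[[nm]]
    expect_true(all(fu$r >= 0))       # rectified weights used in the fusion
  }
})

test_that("architecture accounting follows closed-form oracles", {
  # FLOP scaling: doubling input size quadruples conv FLOPs
  sp <- model_spec(widths = c(6, 12, 12, 24, 48),
                   neck_hidden = c(n3 = 9, td4 = 9, n4 = 9, n5 = 9))
  m <- build_model(sp, seed = 1)
  expect_equal(count_flops(m, 128) / count_flops(m, 64), 4, tolerance = 1e-9)
  p0 <- count_parameters(m)
  expect_equal(count_parameters(m), p0)  # size-independent

  # a hand-enumerated micro network: conv(3->4,k3) params = 3*4*9+2*4
  cv <- ns$mk_conv(3, 4, 3)
  expect_equal(sum(lengths(lapply(cv$pnames, function(p) cv[[p]]))), 116)
  f <- ns$m_flops(cv, 10, 10)
  expect_equal(f$macs, 3 * 4 * 9 * 100)
})
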