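# Architecture blocks and the composed forward pass, checked against the
# naive oracles in helper-fixtures.R.

test_that("stride schedule and level shapes follow the anisotropic design", {
  cfg <- arch_config()
  s <- stride_schedule(cfg)
  expect_equal(nrow(s), 6L)
  expect_true(all(s[, 2:3] == 2L))
  expect_equal(s[, 1], c(1L, 1L, 1L, 1L, 2L, 2L), ignore_attr = TRUE)
  shp <- level_shapes(cfg, c(20, 320, 256))
  expect_equal(shp[7, ], c(D = 5L, H = 5L, W = 4L))
  expect_error(check_patch(cfg, c(20, 300, 256)), "H")
  expect_error(check_patch(cfg, c(18, 320, 256)), "D")
})

test_that("MSC block preserves shape and isolates the residual path", {
  cfg <- tiny_arch()
  set.seed(1)
  w <- network_init(cfg)
  p <- w$encoder[[2]]$msc # 6 -> 6 channels
  x <- array(rnorm(4 * 8 * 8 * 6), c(4, 8, 8, 6, 1))
  y <- msc_block_forward(x, p)
  expect_identical(dim(y), dim(x))
  # zero fusion convolution: output collapses to X' (norm of zero map is the
  # learned shift, zero at init)
  p0 <- p
  p0$fuse$w[] <- 0; p0$fuse$b[] <- 0; p0$fuse$beta[] <- 0
  xp <- strokeseg:::op_leaky_relu(strokeseg:::op_instancenorm(
    strokeseg:::op_conv3d(x, p$conv$w, p$conv$b), p$conv$gamma, p$conv$beta))
  expect_equal(msc_block_forward(x, p0), xp, tolerance = 1e-12)
})

test_that("MSC block matches the nested-loop oracle", {
  cfg <- arch_config(n_levels = 2, channels = c(2L, 3L), msc_kernels = c(5L, 7L),
                     se_levels = 2L, n_d_strides = 1L, ref_patch = c(4L, 8L, 8L),
                     in_channels = 2L)
  set.seed(42)
  w <- network_init(cfg)
  p <- w$encoder[[1]]$msc
  x <- array(rnorm(4 * 8 * 8 * 2), c(4, 8, 8, 2, 1))
  expect_equal(msc_block_forward(x, p), oracle_msc(x, p), tolerance = 1e-5)
  # hand-set depthwise weights on a single-channel 1x1x7 row: explicit loops
  set.seed(7)
  xr <- array(rnorm(7), c(1, 1, 7, 1, 1))
  wdw <- array(c(0.2, -0.5, 1, 0.3, 0, 0.7, -0.1, 0.4, 0.25),
               c(1, 3, 3, 1))
  y <- strokeseg:::op_dwconv3d(xr, wdw, 0.5)
  expect_equal(y, oracle_dwconv3d(xr, wdw, 0.5), tolerance = 1e-12)
})

test_that("SE block annihilates the difference term for symmetric inputs", {
  cfg <- tiny_arch()
  set.seed(3)
  w <- network_init(cfg)
  p <- w$encoder[[2]]$se
  half <- array(rnorm(4 * 8 * 4 * 6), c(4, 8, 4, 6, 1))
  h <- array(0, c(4, 8, 8, 6, 1))
  h[, , 1:4, , ] <- half
  h[, , 8:5, , ] <- half
  dif <- h - h[, , 8:1, , , drop = FALSE]
  expect_true(all(dif == 0))
  out <- se_block_forward(h, p)
  # identical to the same computation with the difference channel zeroed
  cc <- array(0, c(4, 8, 8, 12, 1)); cc[, , , 1:6, ] <- h
  ref <- strokeseg:::op_leaky_relu(strokeseg:::op_instancenorm(
    strokeseg:::op_conv3d(cc, p$w, p$b), p$gamma, p$beta)) + h
  expect_equal(out, ref, tolerance = 0)
  # zero input and zero bias/shift -> zero output
  z <- array(0, dim(h))
  p0 <- p; p0$b[] <- 0; p0$beta[] <- 0
  expect_true(all(se_block_forward(z, p0) == 0))
})

test_that("SE block matches direct evaluation on a small tensor", {
  set.seed(9)
  p <- c(strokeseg:::.init_conv(1L, 1L, 1L, 4L, 2L), strokeseg:::.init_norm(2L))
  h <- array(rnorm(1 * 1 * 4 * 2), c(1, 1, 4, 2, 1))
  expect_equal(se_block_forward(h, p), oracle_se(h, p), tolerance = 1e-6)
})

test_that("attention gate saturates with the psi bias and matches closed form", {
  set.seed(5)
  p <- list(wg = strokeseg:::.init_conv(1, 1, 1, 4, 2),
            wx = strokeseg:::.init_conv(1, 1, 1, 4, 2),
            psi = strokeseg:::.init_conv(1, 1, 1, 2, 1))
  skip <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4, 1))
  gate <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4, 1))
  res <- attention_gate(skip, gate, p, return_coefficients = TRUE)
  expect_true(all(res$attention > 0 & res$attention < 1))
  expect_true(all(abs(res$gated) <= abs(skip) + 1e-12))
  expect_equal(res$gated, oracle_gate(skip, gate, p), tolerance = 1e-6)
  p$psi$b[] <- 50
  expect_equal(attention_gate(skip, gate, p), skip, tolerance = 1e-6)
  p$psi$b[] <- -50
  expect_equal(max(abs(attention_gate(skip, gate, p))), 0, tolerance = 1e-6)
  # 1-voxel toy with scalar weights: closed-form sigmoid expression
  ps <- list(wg = list(w = array(2, c(1, 1, 1, 1, 1)), b = 0.1),
             wx = list(w = array(-1, c(1, 1, 1, 1, 1)), b = 0.2),
             psi = list(w = array(1.5, c(1, 1, 1, 1, 1)), b = -0.3))
  s1 <- array(0.7, c(1, 1, 1, 1, 1)); g1 <- array(0.4, c(1, 1, 1, 1, 1))
  q <- max(2 * 0.4 + 0.1 + (-1) * 0.7 + 0.2, 0)
  a <- 1 / (1 + exp(-(1.5 * q - 0.3)))
  expect_equal(attention_gate(s1, g1, ps)[1], 0.7 * a, tolerance = 1e-12)
})

test_that("forward pass emits the deep-supervision pyramid deterministically", {
  cfg <- tiny_arch()
  set.seed(11)
  w <- network_init(cfg)
  x <- array(rnorm(4 * 8 * 8), c(4, 8, 8, 1, 1))
  lg <- network_forward(x, cfg, w)
  expect_length(lg, 2L)
  expect_identical(dim(lg[[1]]), c(4L, 4L, 4L, 2L, 1L))
  expect_identical(dim(lg[[2]]), c(4L, 8L, 8L, 3L, 1L))
  lg2 <- network_forward(x, cfg, w)
  expect_identical(lg, lg2)
  expect_error(network_forward(array(0, c(5, 8, 8, 1, 1)), cfg, w), "D")
})

test_that("zeroed SE fusion reduces the network to its SE-free ablation", {
  cfg <- tiny_arch()
  set.seed(13)
  w <- network_init(cfg)
  for (l in cfg$se_levels) {
    w$encoder[[l]]$se$w[] <- 0
    w$encoder[[l]]$se$b[] <- 0
    w$encoder[[l]]$se$beta[] <- 0
  }
  cfg_nose <- tiny_arch(se_levels = integer(0))
  w2 <- w
  for (l in cfg$se_levels) w2$encoder[[l]]$se <- NULL
  x <- array(rnorm(4 * 8 * 8), c(4, 8, 8, 1, 1))
  expect_equal(network_forward(x, cfg, w),
               network_forward(x, cfg_nose, w2), tolerance = 1e-12)
})
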