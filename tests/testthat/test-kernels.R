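# Convolution kernels and the autodiff tape, against naive oracles and
# central finite differences.

fd_grad <- function(f, z, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    z1 <- z; z1[i] <- z1[i] + eps
    z2 <- z; z2[i] <- z2[i] - eps
    (f(z1) - f(z2)) / (2 * eps)
  }, numeric(1))
}

test_that("dense convolution matches the nested-loop oracle for all stride patterns", {
  set.seed(1)
  x <- array(rnorm(5 * 6 * 7 * 3 * 2), c(5, 6, 7, 3, 2))
  w <- array(rnorm(3^3 * 3 * 4), c(3, 3, 3, 3, 4))
  b <- rnorm(4)
  for (st in list(c(1L, 1L, 1L), c(1L, 2L, 2L), c(2L, 2L, 2L))) {
    got <- strokeseg:::op_conv3d(x, w, b, stride = st)
    expect_equal(got, oracle_conv3d(x, w, b, st), tolerance = 1e-10)
  }
  expect_error(strokeseg:::op_conv3d(x, array(0, c(3, 3, 3, 2, 4)), b),
               "channel")
})

test_that("conv backward agrees with finite differences", {
  set.seed(2)
  x <- array(rnorm(4 * 5 * 6 * 2), c(4, 5, 6, 2, 1))
  w <- array(rnorm(27 * 2 * 3), c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  r <- array(rnorm(4 * 5 * 6 * 3), c(4, 5, 6, 3, 1))
  xn <- strokeseg:::ag_param(x); wn <- strokeseg:::ag_param(w)
  bn <- strokeseg:::ag_param(b)
  y <- strokeseg:::op_conv3d(xn, wn, bn)
  loss <- strokeseg:::ag_node(sum(y$value * r), list(y),
                              function(g) list(g * r))
  strokeseg:::ag_backward(loss)
  ix <- sample(length(x), 5); iw <- sample(length(w), 5)
  expect_equal(xn$grad[ix],
               fd_grad(function(z) sum(strokeseg:::op_conv3d(z, w, b) * r),
                       x, ix), tolerance = 1e-5)
  expect_equal(wn$grad[iw],
               fd_grad(function(z) sum(strokeseg:::op_conv3d(x, z, b) * r),
                       w, iw), tolerance = 1e-5)
  expect_equal(bn$grad, apply(r, 4, sum), tolerance = 1e-9)
})

test_that("depthwise and transposed convolutions match their oracles and gradients", {
  set.seed(3)
  x <- array(rnorm(4 * 6 * 6 * 3), c(4, 6, 6, 3, 1))
  wd <- array(rnorm(1 * 5 * 5 * 3), c(1, 5, 5, 3)); bd <- rnorm(3)
  expect_equal(strokeseg:::op_dwconv3d(x, wd, bd),
               oracle_dwconv3d(x, wd, bd), tolerance = 1e-10)
  wt <- array(rnorm(3 * 2 * 1 * 2 * 2), c(3, 2, 1, 2, 2)); bt <- rnorm(2)
  y <- strokeseg:::op_convt3d(x, wt, bt)
  expect_identical(dim(y), c(4L, 12L, 12L, 2L, 1L))
  # oracle: scatter each input voxel into its stride block
  yr <- array(0, dim(y))
  for (co in 1:2) yr[, , , co, ] <- bt[co]
  for (ci in 1:3) for (co in 1:2) for (zh in 1:2) for (zw in 1:2)
    for (wi in 1:6) for (hi in 1:6) for (di in 1:4)
      yr[di, (hi - 1) * 2 + zh, (wi - 1) * 2 + zw, co, 1] <-
        yr[di, (hi - 1) * 2 + zh, (wi - 1) * 2 + zw, co, 1] +
        x[di, hi, wi, ci, 1] * wt[ci, co, 1, zh, zw]
  expect_equal(y, yr, tolerance = 1e-10)
  # gradients
  r <- array(rnorm(length(y)), dim(y))
  xn <- strokeseg:::ag_param(x); wn <- strokeseg:::ag_param(wt)
  yn <- strokeseg:::op_convt3d(xn, wn, bt)
  loss <- strokeseg:::ag_node(sum(yn$value * r), list(yn),
                              function(g) list(g * r))
  strokeseg:::ag_backward(loss)
  ix <- sample(length(x), 4)
  expect_equal(xn$grad[ix],
               fd_grad(function(z) sum(strokeseg:::op_convt3d(z, wt, bt) * r),
                       x, ix), tolerance = 1e-5)
})

test_that("instance norm, activations and flips backpropagate correctly", {
  set.seed(4)
  x <- array(rnorm(3 * 4 * 4 * 2), c(3, 4, 4, 2, 1))
  gamma <- c(1.2, 0.8); beta <- c(0.1, -0.2)
  y <- strokeseg:::op_instancenorm(x, gamma, beta)
  expect_equal(y, oracle_instnorm(x, gamma, beta), tolerance = 1e-9)
  xn <- strokeseg:::ag_param(x)
  gn <- strokeseg:::ag_param(gamma); bn <- strokeseg:::ag_param(beta)
  out <- strokeseg:::op_leaky_relu(strokeseg:::op_instancenorm(xn, gn, bn))
  r <- array(rnorm(length(x)), dim(x))
  loss <- strokeseg:::ag_node(sum(out$value * r), list(out),
                              function(g) list(g * r))
  strokeseg:::ag_backward(loss)
  ix <- sample(length(x), 5)
  f <- function(z) sum(strokeseg:::op_leaky_relu(
    strokeseg:::op_instancenorm(z, gamma, beta)) * r)
  expect_equal(xn$grad[ix], fd_grad(f, x, ix), tolerance = 1e-4)
  fg <- function(z) sum(strokeseg:::op_leaky_relu(
    strokeseg:::op_instancenorm(x, z, beta)) * r)
  expect_equal(gn$grad, fd_grad(fg, gamma, 1:2), tolerance = 1e-5)
  # flip is its own inverse and shape-preserving on the tape
  fx <- strokeseg:::op_flip(strokeseg:::op_flip(xn, 3L), 3L)
  expect_equal(fx$value, x)
})

test_that("gradients accumulate across shared sub-expressions", {
  # y = a + a reuses one node twice: grad must be 2
  a <- strokeseg:::ag_param(array(1, c(1, 1, 1, 1, 1)))
  y <- strokeseg:::op_add(a, a)
  loss <- strokeseg:::ag_node(sum(y$value), list(y), function(g)
    list(array(g, c(1, 1, 1, 1, 1))))
  strokeseg:::ag_backward(loss)
  expect_equal(as.numeric(a$grad), 2)
})
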