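# Label pyramid, compound Dice/cross-entropy and the deep-supervision total.

test_that("label pyramid downsamples label-preservingly and merges at 2-class levels", {
  cfg <- tiny_arch()
  lab <- array(sample(0:2, 4 * 8 * 8, TRUE), c(4, 8, 8))
  shapes <- head_shapes(cfg, c(4, 8, 8))
  tg <- downsample_labels(lab, shapes, c(2L, 3L))
  expect_identical(dim(tg[[1]])[1:3], c(4L, 4L, 4L))
  expect_true(all(tg[[1]] %in% 0:1))
  expect_true(all(tg[[2]] %in% 0:2))
  # full-resolution level: unchanged 3-class target
  expect_identical(array(tg[[2]], dim(lab)), lab)
  # 2x downsampling of a 4^3 foreground cube keeps about 2^3 foreground
  cube <- array(0L, c(8, 8, 8)); cube[3:6, 3:6, 3:6] <- 2L
  ds <- downsample_labels(cube, matrix(c(4L, 4L, 4L), 1), 2L)[[1]]
  expect_lte(abs(sum(ds == 1L) - 8L), 1L)
})

test_that("compound loss has the right limits and matches hand arithmetic", {
  # saturated logits toward the truth -> loss ~ 0
  tg <- array(sample(0:1, 4 * 4 * 4, TRUE), c(4, 4, 4))
  z <- array(0, c(4, 4, 4, 2, 1))
  z[, , , 1, 1] <- ifelse(tg == 0, 50, -50)
  z[, , , 2, 1] <- ifelse(tg == 1, 50, -50)
  expect_lt(compound_loss(z, tg), 1e-3)
  # uniform logits, 2 classes: CE = ln 2
  zu <- array(0, c(4, 4, 4, 2, 1))
  expect_equal(compound_loss(zu, tg, alpha = 0, beta = 1), log(2),
               tolerance = 1e-12)
  # hand-built 2x2 single-slice example, one foreground class
  zh <- array(0, c(1, 2, 2, 2, 1))
  zh[1, , , 2, 1] <- c(2, -1, 0.5, 0)   # logit of class 1 per voxel
  th <- array(c(1L, 0L, 1L, 0L), c(1, 2, 2))
  p1 <- 1 / (1 + exp(-c(2, -1, 0.5, 0)))
  g1 <- c(1, 0, 1, 0)
  eps <- 1e-5
  dice <- (2 * sum(p1 * g1) + eps) / (sum(p1) + sum(g1) + eps)
  ce <- -mean(log(ifelse(g1 == 1, p1, 1 - p1)))
  expect_equal(compound_loss(zh, th), (1 - dice) + ce, tolerance = 1e-6)
})

test_that("supervision weights reproduce the printed scheme arithmetic", {
  scheme <- supervision_scheme()
  expect_equal(sum(scheme$res_weights), 1.0, tolerance = 1e-12)
  expect_equal(scheme$res_weights, c(0.02, 0.08, 0.2, 0.1, 0.2, 0.4))
  expect_equal(scheme$classes_per_level, c(2L, 2L, 2L, 3L, 3L, 3L))
  unit_terms <- lapply(seq_len(6), function(i) if (i <= 3) 1 else c(1, 1))
  expect_equal(supervision_total(scheme, unit_terms), 1.7, tolerance = 1e-12)
})

test_that("hierarchical total vanishes for perfect predictions and validates inputs", {
  scheme <- supervision_scheme(n_levels = 2, classes_per_level = c(2L, 3L))
  t2 <- array(sample(0:1, 2 * 4 * 4, TRUE), c(2, 4, 4, 1))
  t3 <- array(sample(0:2, 4 * 8 * 8, TRUE), c(4, 8, 8, 1))
  mk <- function(tg, K) {
    z <- array(-50, c(dim(tg)[1:3], K, 1))
    for (k in seq_len(K)) z[, , , k, 1][tg[, , , 1] == k - 1] <- 50
    z
  }
  tot <- hierarchical_total_loss(list(mk(t2, 2), mk(t3, 3)),
                                 list(t2, t3), scheme)
  expect_lt(tot, 1e-2)
  expect_gte(tot, 0)
  expect_error(hierarchical_total_loss(list(mk(t2, 2)), list(t2), scheme),
               "level count")
  expect_error(hierarchical_total_loss(list(mk(t2, 3), mk(t3, 3)),
                                       list(t2, t3), scheme), "classes")
})

test_that("ce_mode doubles the shared cross-entropy at 3-class levels", {
  set.seed(2)
  tg <- array(sample(0:2, 4 * 4 * 4, TRUE), c(4, 4, 4))
  z <- array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3, 1))
  shared <- strokeseg:::.seg_loss(z, tg, alpha = 0, beta = 1, fg_reduce = "sum")
  per_class <- strokeseg:::.seg_loss(z, tg, alpha = 0, beta = 2,
                                     fg_reduce = "sum")
  expect_equal(per_class, 2 * shared, tolerance = 1e-12)
})

test_that("Dice term is permutation-invariant and CE is monotone", {
  set.seed(3)
  tg <- array(sample(0:1, 64, TRUE), c(4, 4, 4))
  z <- array(rnorm(128), c(4, 4, 4, 2, 1))
  base <- compound_loss(z, tg, beta = 0)
  perm <- sample(64)
  zp <- array(0, dim(z))
  for (k in 1:2) zp[, , , k, 1] <- array(z[, , , k, 1][perm], c(4, 4, 4))
  tp <- array(tg[perm], c(4, 4, 4))
  expect_equal(compound_loss(zp, tp, beta = 0), base, tolerance = 1e-12)
  # raising the true-class logit at one voxel never increases the CE
  v <- c(2, 1, 1)
  z2 <- z
  k <- tg[v[1], v[2], v[3]] + 1
  z2[v[1], v[2], v[3], k, 1] <- z2[v[1], v[2], v[3], k, 1] + 1
  expect_lte(compound_loss(z2, tg, alpha = 0), compound_loss(z, tg, alpha = 0))
})

test_that("zeroing a level weight removes its gradient contribution", {
  cfg <- tiny_arch()
  set.seed(4)
  w <- network_init(cfg)
  x <- array(rnorm(4 * 8 * 8), c(4, 8, 8, 1, 1))
  lab <- array(sample(0:2, 4 * 8 * 8, TRUE), c(4, 8, 8, 1))
  shapes <- head_shapes(cfg, c(4, 8, 8))
  grad_of <- function(res) {
    scheme <- supervision_scheme(n_levels = 2, res_weights = res,
                                 classes_per_level = cfg$head_classes)
    nodes <- strokeseg:::params_to_nodes(w)
    tg <- downsample_labels(lab, shapes, scheme$classes_per_level)
    loss <- hierarchical_total_loss(network_forward(x, cfg, nodes), tg, scheme)
    strokeseg:::ag_backward(loss)
    # gradient of the deepest head's weights
    nodes$decoder[[1]]$head$w$grad
  }
  g_on <- grad_of(c(0.5, 0.5))
  g_off <- grad_of(c(0, 1))
  expect_gt(max(abs(g_on)), 0)
  expect_true(is.null(g_off) || max(abs(g_off)) == 0)
})
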