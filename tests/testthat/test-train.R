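# Patch sampling, augmentation, the LR schedule and the optimisation loop.

test_that("polynomial schedule hits its endpoints and midpoint", {
  cfg <- train_config(epochs = 300L)
  expect_equal(poly_lr(0, cfg), 1e-2)
  expect_equal(poly_lr(300, cfg), 0)
  expect_equal(poly_lr(150, cfg), 1e-2 * 0.5^0.9, tolerance = 1e-12)
  expect_error(poly_lr(-1, cfg), "range")
})

test_that("patch sampling covers exact-size cases and forces foreground", {
  img <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  lab <- array(0L, c(4, 8, 8)); lab[2, 5, 6] <- 1L
  set.seed(1)
  pt <- sample_patch(img, lab, c(4L, 8L, 8L), fg_prob = 0)
  expect_identical(pt$image, img)
  # one lesion voxel, fg_prob = 1: every patch contains it
  big <- array(rnorm(8 * 32 * 32), c(8, 32, 32))
  bl <- array(0L, c(8, 32, 32)); bl[5, 17, 9] <- 1L
  for (i in 1:10) {
    pt <- sample_patch(big, bl, c(4L, 8L, 8L), fg_prob = 1)
    expect_equal(sum(pt$label), 1L)
  }
  # undersized cases are padded up to the patch
  pt <- sample_patch(img, lab, c(8L, 8L, 8L), fg_prob = 1)
  expect_identical(dim(pt$image), c(8L, 8L, 8L))
  expect_equal(sum(pt$label), 1L)
  # seeded reproducibility
  set.seed(99); a <- sample_patch(big, bl, c(4L, 8L, 8L), 0.5)
  set.seed(99); b <- sample_patch(big, bl, c(4L, 8L, 8L), 0.5)
  expect_identical(a, b)
})

test_that("augmentation is the identity when off and conserves labels under mirroring", {
  set.seed(5)
  img <- array(rnorm(4 * 16 * 16), c(4, 16, 16))
  lab <- array(0L, dim(img)); lab[2:3, 3:6, 2:5] <- 1L
  out <- augment_patch(img, lab, augment_off())
  expect_identical(out$image, img)
  expect_identical(out$label, lab)
  # force a W mirror only
  pm <- augment_params(p_rotation = 0, p_scaling = 0, p_elastic = 0,
                       p_mirror = 1, p_noise = 0, p_blur = 0, p_lowres = 0,
                       p_gamma = 0, p_contrast = 0, p_brightness = 0,
                       mirror_axes = c(FALSE, FALSE, TRUE))
  out <- augment_patch(img, lab, pm)
  expect_equal(sum(out$label), sum(lab))
  ctr <- function(l) colMeans(which(l == 1L, arr.ind = TRUE))
  c0 <- ctr(lab); c1 <- ctr(out$label)
  expect_equal(c1[["dim1"]], c0[["dim1"]])
  expect_equal(c1[["dim3"]], dim(lab)[3] + 1 - c0[["dim3"]])
  # shapes survive every transform and reruns are seed-reproducible
  pall <- augment_params(p_rotation = 1, p_scaling = 1, p_elastic = 1,
                         p_mirror = 1, p_noise = 1, p_blur = 1, p_lowres = 1,
                         p_gamma = 1, p_contrast = 1, p_brightness = 1)
  set.seed(3); a <- augment_patch(img, lab, pall)
  set.seed(3); b <- augment_patch(img, lab, pall)
  expect_identical(dim(a$image), dim(img))
  expect_true(all(a$label %in% 0:1))
  expect_identical(a, b)
})

test_that("gradient clipping bounds the global norm", {
  p1 <- strokeseg:::ag_param(array(0, c(2, 2)))
  p2 <- strokeseg:::ag_param(array(0, 3))
  p1$grad <- array(30, c(2, 2)); p2$grad <- array(-40, 3)
  pre <- sqrt(sum(p1$grad^2) + sum(p2$grad^2))
  nrm <- strokeseg:::.clip_grads(list(p1, p2), 12)
  expect_equal(nrm, pre)
  post <- sqrt(sum(p1$grad^2) + sum(p2$grad^2))
  expect_equal(post, 12, tolerance = 1e-12)
  # below the threshold nothing changes
  p1$grad <- array(0.1, c(2, 2)); p2$grad <- array(0.1, 3)
  strokeseg:::.clip_grads(list(p1, p2), 12)
  expect_equal(p1$grad, array(0.1, c(2, 2)))
})

train_fixture <- function(n = 2, seed = 21) {
  r <- phantom_ranges(ic_scale = c(0.8, 1.2), ip_ic_ratio = c(2, 4),
                      center_h = c(-2, 2), center_w = c(3.5, 4.5))
  ch <- generate_cohort(n, ranges = r, seed = seed,
                        base = tiny_phantom_params())
  fp <- compute_fingerprint(ch$cases)
  list(cases = lapply(ch$cases, preprocess_case, fp = fp), fp = fp,
       cohort = ch)
}

test_that("training runs are seed-reproducible and zero LR freezes weights", {
  fx <- train_fixture()
  cfg <- tiny_arch(ref_patch = c(4L, 16L, 16L))
  tcfg <- train_config(patch_size = c(4L, 16L, 16L), batch_size = 1L,
                       epochs = 2L, iters_per_epoch = 3L, seed = 31L,
                       augment = augment_off())
  f1 <- train_loop(fx$cases, cfg, tcfg)
  f2 <- train_loop(fx$cases, cfg, tcfg)
  expect_equal(f1$loss_log$loss, f2$loss_log$loss, tolerance = 1e-4)
  expect_equal(nrow(f1$loss_log), 6L)
  # lr0 = 0: weights unchanged from initialisation
  tcfg0 <- train_config(patch_size = c(4L, 16L, 16L), batch_size = 1L,
                        epochs = 1L, iters_per_epoch = 2L, lr0 = 0,
                        seed = 31L, augment = augment_off())
  f0 <- train_loop(fx$cases, cfg, tcfg0)
  set.seed(31L)
  init <- network_init(cfg)
  expect_equal(f0$weights$stem$w, init$stem$w, tolerance = 0)
})

test_that("the fitted model object exposes the usual verbs", {
  fx <- train_fixture()
  cfg <- tiny_arch(ref_patch = c(4L, 16L, 16L))
  tcfg <- train_config(patch_size = c(4L, 16L, 16L), batch_size = 1L,
                       epochs = 2L, iters_per_epoch = 2L, seed = 8L,
                       augment = augment_off())
  m <- strokeseg_fit(fx$cases, fingerprint = fx$fp, arch = cfg, train = tcfg)
  expect_s3_class(m, "strokeseg_model")
  expect_output(print(m), "levels")
  s <- summary(m)
  expect_gt(s$n_parameters, 0)
  expect_type(coef(m), "list")
  cs <- fx$cohort$cases[[1]]
  pr <- predict(m, cs$image, cs$spacing, tta = FALSE)
  expect_identical(dim(pr), dim(cs$label))
  expect_true(all(pr %in% 0:2))
})
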