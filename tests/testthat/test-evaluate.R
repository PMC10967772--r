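# Overlap/surface metrics, volumetry, agreement and dichotomisation.

test_that("DSC follows its definition and conventions", {
  m <- array(FALSE, c(3, 3, 3)); m[1:2, 1, 1] <- TRUE
  expect_equal(dsc(m, m), 100)
  n <- array(FALSE, c(3, 3, 3)); n[3, 3, 3] <- TRUE
  expect_equal(dsc(m, n), 0)
  a <- array(FALSE, c(4, 4, 4)); a[1:4, 1, 1] <- TRUE          # |A| = 4
  b <- array(FALSE, c(4, 4, 4)); b[1:4, 1:2, 1] <- TRUE        # |B| = 8
  expect_equal(dsc(a, b), 2 * 4 / 12 * 100, tolerance = 1e-9)
  e <- array(FALSE, c(2, 2, 2))
  expect_equal(dsc(e, e), 100)    # both empty
  expect_equal(dsc(a, array(FALSE, c(4, 4, 4))), 0)
  expect_error(dsc(a, e), "shapes")
  # symmetry
  expect_equal(dsc(a, b), dsc(b, a))
})

test_that("surface distances: identical masks, the 5 mm two-voxel case, and empties", {
  m <- array(FALSE, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- TRUE
  sd0 <- surface_distances(m, m, c(5, 0.4, 0.4))
  expect_equal(sd0$hd95, 0); expect_equal(sd0$assd, 0)
  a <- array(FALSE, c(3, 3, 3)); a[1, 2, 2] <- TRUE
  b <- array(FALSE, c(3, 3, 3)); b[2, 2, 2] <- TRUE
  sd1 <- surface_distances(a, b, c(5, 0.4, 0.4))
  expect_equal(sd1$hd95, 5.0); expect_equal(sd1$assd, 5.0)
  sde <- surface_distances(array(FALSE, c(3, 3, 3)), b, c(1, 1, 1))
  expect_false(sde$defined)
  expect_true(is.na(sde$hd95))
})

test_that("surface distances agree with a pure-R brute-force oracle", {
  set.seed(4)
  spacing <- c(5, 0.4, 0.4)
  for (i in 1:4) {
    a <- array(stats::runif(8 * 10 * 10) < 0.2, c(8, 10, 10))
    b <- array(stats::runif(8 * 10 * 10) < 0.2, c(8, 10, 10))
    if (!any(a) || !any(b)) next
    got <- surface_distances(a, b, spacing)
    ref <- oracle_surface(a, b, spacing)
    expect_equal(got$hd95, ref$hd95, tolerance = 1e-6)
    expect_equal(got$assd, ref$assd, tolerance = 1e-6)
  }
})

test_that("lesion volume is voxel count times voxel volume", {
  m <- array(FALSE, c(10, 10, 10)); m[seq_len(1000)] <- TRUE
  expect_equal(lesion_volume_ml(m, c(5, 0.4, 0.4)), 0.8)
  expect_equal(lesion_volume_ml(array(FALSE, c(2, 2, 2)), c(1, 1, 1)), 0)
  ph <- generate_phantom(phantom_params())
  vic <- lesion_volume_ml(ph$label == 2L, ph$spacing)
  expect_lt(abs(vic - ph$manifest[["vol_ic_ml"]]) / ph$manifest[["vol_ic_ml"]],
            0.10)
})

test_that("volume agreement reproduces textbook formulas", {
  x <- c(10, 20, 35, 50, 80)
  y <- c(12, 18, 40, 47, 85)
  va <- volume_agreement(y, x)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(va$r, r_hand, tolerance = 1e-6)
  z <- atanh(r_hand); se <- 1 / sqrt(5 - 3)
  expect_equal(va$ci, tanh(c(z - 1.96 * se, z + 1.96 * se)), tolerance = 1e-3)
  d <- y - x
  expect_equal(va$bias, mean(d))
  expect_equal(unname(va$loa), mean(d) + c(-1.96, 1.96) * stats::sd(d))
  expect_equal(volume_agreement(x, x)$r, 1)
  expect_equal(volume_agreement(-x, x)$r, -1)
  expect_error(volume_agreement(rep(1, 5), x), "variance")
})

test_that("dichotomisation reproduces contingency arithmetic and edge cases", {
  # toy table TP=9 TN=26 FP=2 FN=3 around a 70 mL cut-off
  true_vol <- c(rep(100, 12), rep(30, 28))           # 12 positive, 28 negative
  pred_vol <- c(rep(100, 9), rep(30, 3),             # 9 TP, 3 FN
                rep(100, 2), rep(30, 26))            # 2 FP, 26 TN
  dv <- dichotomize_volumes(pred_vol, true_vol, cutoff = 70)
  expect_equal(dv$accuracy, 87.5, tolerance = 1e-9)
  po <- 35 / 40
  pe <- (12 / 40) * (11 / 40) + (28 / 40) * (29 / 40)
  expect_equal(dv$kappa, (po - pe) / (1 - pe), tolerance = 1e-9)
  # perfect agreement
  dp <- dichotomize_volumes(true_vol, true_vol, cutoff = 70)
  expect_equal(dp$accuracy, 100)
  expect_equal(dp$kappa, 1)
  expect_equal(dp$auc, 1)
  # constant predictions: chance agreement, kappa 0
  dc <- dichotomize_volumes(rep(30, 40), true_vol, cutoff = 70)
  expect_equal(dc$kappa, 0)
  # single-class truth: kappa/AUC flagged undefined
  du <- dichotomize_volumes(pred_vol, rep(30, 40), cutoff = 70)
  expect_false(du$defined)
  expect_true(is.na(du$auc))
})

test_that("cohort evaluation is consistent with per-case recomputation", {
  set.seed(6)
  r <- phantom_ranges(ic_scale = c(0.8, 1.2), ip_ic_ratio = c(2, 4),
                      center_h = c(-2, 2), center_w = c(3.5, 4.5))
  ch <- generate_cohort(4, ranges = r, seed = 9, base = tiny_phantom_params())
  truths <- lapply(ch$cases, `[[`, "label")
  # perturbed predictions: drop one axial slice of the lesion
  preds <- lapply(truths, function(l) { l2 <- l; l2[1:2, , ] <- 0L; l2 })
  ev <- evaluate_cohort(truths, preds, ch$cases[[1]]$spacing, cutoff = NULL)
  expect_equal(nrow(ev$per_case), 12L)
  for (tg in c("ip", "ic", "total")) {
    rows <- ev$per_case[ev$per_case$target == tg, ]
    srow <- ev$summary[ev$summary$target == tg, ]
    expect_equal(srow$dsc_mean, mean(rows$dsc))
    expect_equal(srow$dsc_sd, stats::sd(rows$dsc))
  }
  # merged-mask identity: total DSC equals dsc on merged masks
  i <- 2
  expect_equal(ev$per_case$dsc[ev$per_case$target == "total" &
                                 ev$per_case$case == i],
               dsc(preds[[i]] > 0, truths[[i]] > 0))
  # identical predictions: perfect metrics
  ev2 <- evaluate_cohort(truths, truths, ch$cases[[1]]$spacing, cutoff = NULL)
  expect_true(all(ev2$per_case$dsc == 100))
  expect_true(all(ev2$per_case$hd95 == 0))
  expect_equal(ev2$dichotomization$kappa, 1)
  expect_error(evaluate_cohort(truths, preds[1:2], ch$cases[[1]]$spacing),
               "unpaired")
})

test_that("subgroup splits report two-sample comparisons", {
  set.seed(8)
  true_vol <- runif(12, 1, 6)
  truths <- lapply(true_vol, function(v) {
    m <- array(0L, c(4, 10, 10)); m[seq_len(round(v * 50))] <- 2L; m
  })
  preds <- truths
  meta <- data.frame(sex = rep(c("f", "m"), 6))
  ev <- evaluate_cohort(truths, preds, c(5, 1, 1), cutoff = NULL,
                        metadata = meta)
  expect_length(ev$subgroups, 1L)
  expect_equal(ev$subgroups[[1]]$variable, "sex")
  expect_true(all(ev$subgroups[[1]]$accuracy_by_level == 100))
})
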