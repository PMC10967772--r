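# Fingerprint, crop, resample, normalisation and geometry restoration.

make_case <- function(seed = 1, spacing = c(5, 0.4, 0.4)) {
  set.seed(seed)
  img <- array(stats::rnorm(8 * 16 * 12, mean = 30, sd = 3), c(8, 16, 12))
  lab <- array(0L, dim(img))
  lab[3:5, 6:10, 4:8] <- 1L
  lab[4, 7:9, 5:7] <- 2L
  list(image = img, label = lab, spacing = spacing)
}

test_that("fingerprint pools foreground stats and takes per-axis median spacing", {
  cases <- list(make_case(1, c(4.999, 0.38, 0.40)),
                make_case(2, c(5.0, 0.37, 0.41)),
                make_case(3, c(5.015, 0.39, 0.39)))
  fp <- compute_fingerprint(cases)
  expect_s3_class(fp, "dataset_fingerprint")
  expect_equal(fp$median_spacing, c(5.0, 0.38, 0.40))
  fg <- unlist(lapply(cases, function(cs) cs$image[cs$label > 0]))
  q <- stats::quantile(fg, c(0.005, 0.995), names = FALSE)
  expect_equal(c(fp$clip_low, fp$clip_high), q)
  clipped <- pmin(pmax(fg, q[1]), q[2])
  expect_equal(fp$fg_mean, mean(clipped))
  expect_equal(fp$fg_std, stats::sd(clipped))
})

test_that("degenerate constant-foreground cohort is rejected", {
  cs <- make_case()
  cs$image[cs$label > 0] <- 7
  expect_error(compute_fingerprint(list(cs)), "degenerate|variance")
  cs$label[] <- 0L
  expect_error(compute_fingerprint(list(cs)), "foreground")
})

test_that("fingerprint JSON round-trips", {
  fp <- compute_fingerprint(list(make_case()))
  path <- withr::local_tempfile(fileext = ".json")
  write_fingerprint(fp, path)
  fp2 <- read_fingerprint(path)
  expect_equal(fp$median_spacing, fp2$median_spacing)
  expect_equal(fp$fg_mean, fp2$fg_mean)
})

test_that("crop finds the tight bounding box and restores exactly", {
  img <- array(0, c(8, 10, 12))
  img[3:5, 4:7, 2:9] <- 1 # zero-based boxes [2,5) x [3,7) x [1,9)
  cr <- crop_to_foreground(img, NULL, c(5, 0.4, 0.4), threshold = 0)
  expect_identical(dim(cr$image), c(3L, 4L, 8L))
  expect_identical(cr$record$box_start, c(3L, 4L, 2L))
  expect_identical(cr$record$box_stop, c(6L, 8L, 10L))
  # all-nonzero volume: identity crop
  full <- crop_to_foreground(array(1, c(4, 4, 4)), NULL, c(1, 1, 1),
                             threshold = 0)
  expect_identical(dim(full$image), c(4L, 4L, 4L))
  expect_identical(full$record$box_start, c(1L, 1L, 1L))
  expect_error(crop_to_foreground(array(0, c(3, 3, 3)), NULL, c(1, 1, 1),
                                  threshold = 0), "empty")
})

test_that("resample follows the rounding rule and preserves labels", {
  x <- array(seq_len(10), c(10, 1, 1))
  r <- resample_volume(x, c(1, 1, 1), c(2, 1, 1))
  expect_identical(dim(r$x), c(5L, 1L, 1L))
  # identity when target equals source
  r2 <- resample_volume(x, c(1, 1, 1), c(1, 1, 1))
  expect_identical(r2$x, x)
  lab <- array(sample(0:2, 6 * 8 * 8, TRUE), c(6, 8, 8))
  rl <- resample_volume(lab, c(5, 0.4, 0.4), c(5, 0.8, 0.8),
                        method = "nearest")
  expect_true(all(rl$x %in% 0:2))
  expect_true(is.integer(rl$x))
  expect_error(resample_volume(x, c(1, 1, 1), c(0, 1, 1)), "positive")
})

test_that("normalisation clips, centres and is monotone", {
  cases <- list(make_case())
  fp <- compute_fingerprint(cases)
  expect_equal(normalize_volume(array(fp$fg_mean, c(1, 1, 1)), fp)[1], 0)
  expect_equal(normalize_volume(array(fp$clip_high + 100, c(1, 1, 1)), fp)[1],
               (fp$clip_high - fp$fg_mean) / fp$fg_std)
  # applying to the fingerprint's own pooled foreground gives mean 0, sd <= 1
  fg <- cases[[1]]$image[cases[[1]]$label > 0]
  z <- normalize_volume(array(fg, c(length(fg), 1, 1)), fp)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lte(stats::sd(z), 1 + 1e-9)
  # monotone non-decreasing
  xs <- seq(fp$clip_low - 5, fp$clip_high + 5, length.out = 101)
  ys <- normalize_volume(array(xs, c(101, 1, 1)), fp)
  expect_true(all(diff(ys) >= 0))
})

test_that("preprocess-then-restore recovers native shape and volumes", {
  ph <- generate_phantom(phantom_params())
  cases <- list(list(image = ph$image, label = ph$label, spacing = ph$spacing))
  fp <- compute_fingerprint(cases)
  fp$median_spacing <- c(5, 0.5, 0.5) # force a real resampling step
  pre <- preprocess_case(cases[[1]], fp)
  expect_identical(dim(pre$image), dim(pre$label))
  back <- restore_geometry(pre$label, pre$record, fp)
  expect_identical(dim(back), dim(ph$label))
  expect_true(all(back %in% 0:2))
  for (lv in 1:2) {
    v0 <- sum(ph$label == lv) * prod(ph$spacing) / 1000
    v1 <- sum(back == lv) * prod(ph$spacing) / 1000
    expect_lt(abs(v1 - v0) / v0, 0.10)
  }
  # all-background prediction restores to all background
  empty <- array(0L, dim(pre$label))
  expect_true(all(restore_geometry(empty, pre$record, fp) == 0L))
})
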