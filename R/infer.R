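# Gaussian-weighted sliding-window inference with flip test-time
# augmentation, and the raw-volume prediction pipeline (preprocess ->
# predict -> restore to native geometry).  The final segmentation uses only
# the full-resolution 3-class head; deep-supervision heads are
# training-only.  No morphological post-processing is applied.

#' Separable Gaussian importance map
#'
#' Peak 1 at the patch centre, per-axis sigma `sigma_scale * extent`, all
#' weights strictly positive and symmetric under flipping any axis.
#'
#' @param patch_size (D,H,W).
#' @param sigma_scale sigma as a fraction of the extent (default 1/8).
#' @return (D,H,W) weight array.
#' @export
gaussian_importance_map <- function(patch_size, sigma_scale = 1 / 8) {
  if (any(patch_size < 1)) stop("patch extents must be positive")
  g1 <- function(n) {
    ctr <- (n - 1) / 2
    s <- max(sigma_scale * n, 1e-8)
    exp(-((seq_len(n) - 1 - ctr)^2) / (2 * s^2))
  }
  w <- outer(outer(g1(patch_size[1]), g1(patch_size[2])), g1(patch_size[3]))
  array(w / max(w), patch_size)
}

# window start offsets (1-based) covering `size` with `patch`-sized windows
# at stride `overlap * patch`, last window aligned to the far edge
.window_starts <- function(size, patch, overlap = 0.5) {
  if (size <= patch) return(1L)
  stride <- max(1L, as.integer(round(patch * overlap)))
  st <- seq.int(1L, size - patch + 1L, by = stride)
  if (st[length(st)] != size - patch + 1L) st <- c(st, size - patch + 1L)
  unique(st)
}

# build a probability-predictor closure from weights: (D,H,W) patch array ->
# (D,H,W,K) softmax probabilities of the full-resolution head
.net_predictor <- function(cfg, weights) {
  function(patch) {
    x <- array(patch, c(dim(patch), 1L, 1L))
    logits <- network_forward(x, cfg, weights)
    z <- ag_value(logits[[cfg$n_levels - 1L]])
    dm <- dim(z)
    zm <- matrix(z, prod(dm[1:3]), dm[4])
    p <- .softmax_rows(zm)
    array(p, c(dm[1:3], dm[4]))
  }
}

#' Gaussian-weighted sliding-window prediction
#'
#' Tiles the (preprocessed) volume with patch-sized windows at
#' `overlap x patch` stride (final windows aligned to the far edges), runs
#' the predictor on each window, and accumulates the per-window class
#' probabilities under the Gaussian importance map; the accumulated weight
#' is normalised out so per-voxel probabilities still sum to one.
#'
#' @param image (D,H,W) preprocessed array (padded here if smaller than the
#'   patch; the padding is removed again).
#' @param predictor function mapping a (D,H,W) patch to a (D,H,W,K)
#'   probability array, or a `strokeseg_model`.
#' @param patch_size window size (D,H,W).
#' @param overlap stride as a fraction of the patch (default 0.5).
#' @param pad_value fill used when the volume is smaller than the patch
#'   (default the volume minimum).
#' @return (D,H,W,K) probability array over the input grid.
#' @export
sliding_window_predict <- function(image, predictor, patch_size,
                                   overlap = 0.5, pad_value = NULL) {
  if (inherits(predictor, "strokeseg_model"))
    predictor <- .net_predictor(predictor$arch, predictor$weights)
  orig_shape <- dim(image)
  if (is.null(pad_value)) pad_value <- min(image)
  padded <- .pad_to(image, patch_size, pad_value)
  image <- padded$x
  shp <- dim(image)
  wmap <- gaussian_importance_map(patch_size)
  starts <- lapply(1:3, function(a) .window_starts(shp[a], patch_size[a], overlap))
  acc <- NULL
  wacc <- array(0, shp)
  for (sd_ in starts[[1]]) for (sh in starts[[2]]) for (sw in starts[[3]]) {
    ii <- sd_ + seq_len(patch_size[1]) - 1L
    jj <- sh + seq_len(patch_size[2]) - 1L
    kk <- sw + seq_len(patch_size[3]) - 1L
    pr <- predictor(image[ii, jj, kk, drop = FALSE])
    K <- dim(pr)[4]
    if (is.null(acc)) acc <- array(0, c(shp, K))
    acc[ii, jj, kk, ] <- acc[ii, jj, kk, , drop = FALSE] +
      pr * as.vector(wmap)
    wacc[ii, jj, kk] <- wacc[ii, jj, kk] + wmap
  }
  K <- dim(acc)[4]
  out <- acc / array(wacc, c(shp, K))
  # un-pad
  lo <- padded$lo
  out[lo[1] + seq_len(orig_shape[1]), lo[2] + seq_len(orig_shape[2]),
      lo[3] + seq_len(orig_shape[3]), , drop = FALSE]
}

#' Flip test-time augmentation
#'
#' Averages [sliding_window_predict()] over all 8 combinations of flipping
#' the three spatial axes, un-flipping each prediction before averaging.
#'
#' @inheritParams sliding_window_predict
#' @return (D,H,W,K) probability array.
#' @export
tta_predict <- function(image, predictor, patch_size, overlap = 0.5,
                        pad_value = NULL) {
  if (inherits(predictor, "strokeseg_model"))
    predictor <- .net_predictor(predictor$arch, predictor$weights)
  flips <- expand.grid(d = c(FALSE, TRUE), h = c(FALSE, TRUE),
                       w = c(FALSE, TRUE))
  acc <- NULL
  for (i in seq_len(nrow(flips))) {
    f <- as.logical(flips[i, ])
    img <- image
    if (f[1]) img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
    if (f[2]) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
    if (f[3]) img <- img[, , rev(seq_len(dim(img)[3])), drop = FALSE]
    pr <- sliding_window_predict(img, predictor, patch_size, overlap,
                                 pad_value)
    if (f[1]) pr <- pr[rev(seq_len(dim(pr)[1])), , , , drop = FALSE]
    if (f[2]) pr <- pr[, rev(seq_len(dim(pr)[2])), , , drop = FALSE]
    if (f[3]) pr <- pr[, , rev(seq_len(dim(pr)[3])), , drop = FALSE]
    acc <- if (is.null(acc)) pr else acc + pr
  }
  acc / nrow(flips)
}

#' Argmax class map from probabilities (ties -> lowest class index)
#' @param prob (D,H,W,K) array.
#' @return integer (D,H,W) array of 0-based class labels.
#' @export
prob_to_labels <- function(prob) {
  dm <- dim(prob)
  pm <- matrix(prob, prod(dm[1:3]), dm[4])
  lab <- max.col(pm, ties.method = "first") - 1L
  array(as.integer(lab), dm[1:3])
}

#' Predict one raw case in native geometry
#'
#' Crop, resample to the fingerprint spacing, normalise, run flip-TTA
#' Gaussian sliding-window prediction, take the voxelwise argmax of the
#' full-resolution 3-class head, and restore to the original geometry.
#'
#' @param image raw (D,H,W) array.
#' @param spacing (D,H,W) spacing in mm.
#' @param model a `strokeseg_model` (or list with `arch`, `weights`,
#'   `fingerprint`, `train`).
#' @param tta use flip test-time augmentation (default TRUE).
#' @param overlap sliding-window stride fraction.
#' @return integer (D,H,W) label map over `{0,1,2}`, same shape as `image`.
#' @export
predict_case <- function(image, spacing, model, tta = TRUE, overlap = 0.5) {
  fp <- model$fingerprint
  if (is.null(fp)) stop("model carries no fingerprint")
  pre <- preprocess_case(list(image = image, spacing = spacing), fp)
  predictor <- .net_predictor(model$arch, model$weights)
  patch <- model$train$patch_size
  pad_value <- (fp$clip_low - fp$fg_mean) / fp$fg_std
  prob <- if (tta) {
    tta_predict(pre$image, predictor, patch, overlap, pad_value)
  } else {
    sliding_window_predict(pre$image, predictor, patch, overlap, pad_value)
  }
  lab <- prob_to_labels(prob)
  restore_geometry(lab, pre$record, fp)
}
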