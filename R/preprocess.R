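# Fingerprint-driven preprocessing: crop to the brain bounding box, resample
# every case to the cohort's median voxel spacing, and z-score normalise
# intensities inside the percentile-clipped window of the segmentation
# target.  A crop record makes the pipeline invertible so predictions can be
# scored in native geometry.
#
# Cases are plain lists: `image` (D,H,W numeric array), optional `label`
# (integer array, same shape), `spacing` (mm, (D,H,W)).

#' Compute the dataset fingerprint
#'
#' The target spacing is the per-axis median of the training spacings.  The
#' intensity statistics pool all foreground voxels (label > 0 — the
#' segmentation target) over the training cases: the clip window is their
#' 0.5th/99.5th percentile and the z-score mean/sd are taken over the pooled
#' values after clipping.
#'
#' @param cases list of cases with `image`, `label` and `spacing`.
#' @param clip_quantiles lower/upper pooled-foreground percentile bounds.
#' @return object of class `dataset_fingerprint` with fields
#'   `median_spacing`, `clip_low`, `clip_high`, `fg_mean`, `fg_std`.
#' @export
compute_fingerprint <- function(cases, clip_quantiles = c(0.005, 0.995)) {
  if (length(cases) < 1) stop("at least one training case is required")
  sp <- t(vapply(cases, function(cs) cs$spacing, numeric(3)))
  med <- apply(sp, 2, stats::median)
  fg <- unlist(lapply(cases, function(cs) {
    if (is.null(cs$label)) stop("fingerprint cases need labels")
    cs$image[cs$label > 0L]
  }), use.names = FALSE)
  if (length(fg) == 0) stop("no foreground voxel in the cohort")
  q <- stats::quantile(fg, clip_quantiles, names = FALSE)
  if (!(q[1] < q[2]))
    stop("degenerate foreground intensity window (clip_low >= clip_high)")
  clipped <- pmin(pmax(fg, q[1]), q[2])
  fstd <- stats::sd(clipped)
  if (!is.finite(fstd) || fstd < 1e-8)
    stop("foreground intensities have (near-)zero variance")
  structure(list(median_spacing = med, clip_low = q[1], clip_high = q[2],
                 fg_mean = mean(clipped), fg_std = fstd),
            class = "dataset_fingerprint")
}

#' Write / read a fingerprint as JSON
#' @param fp a `dataset_fingerprint`.
#' @param path file path.
#' @export
write_fingerprint <- function(fp, path) {
  jsonlite::write_json(unclass(fp), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fingerprint
#' @export
read_fingerprint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(median_spacing = as.numeric(x$median_spacing),
                 clip_low = x$clip_low, clip_high = x$clip_high,
                 fg_mean = x$fg_mean, fg_std = x$fg_std),
            class = "dataset_fingerprint")
}

#' Crop a volume to its foreground bounding box
#'
#' The brain-mask proxy is "strictly above `threshold`"; the default
#' threshold is the volume minimum, i.e. everything brighter than the
#' emptiest voxel counts as tissue (inputs are assumed skull-stripped).
#'
#' @param image (D,H,W) array.
#' @param label optional aligned integer array, cropped identically.
#' @param spacing (D,H,W) voxel spacing in mm.
#' @param threshold intensity threshold; voxels `> threshold` are foreground.
#' @return list with `image`, `label` (or NULL) and `record` (a
#'   `crop_record`: original shape, per-axis box start/stop, spacing).
#' @export
crop_to_foreground <- function(image, label = NULL, spacing,
                               threshold = NULL) {
  if (is.null(threshold)) threshold <- min(image)
  mask <- image > threshold
  if (!any(mask)) stop("no voxel above the crop threshold (empty volume)")
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  rec <- structure(list(original_shape = dim(image),
                        box_start = as.integer(lo),
                        box_stop = as.integer(hi + 1L),   # exclusive
                        spacing = spacing),
                   class = "crop_record")
  img <- image[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  lab <- if (!is.null(label))
    label[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  list(image = img, label = lab, record = rec)
}

#' Resample a scalar volume or a label map
#'
#' Output shape per axis is `round(shape * spacing / target)` (half away
#' from zero, floored at one voxel), or an explicitly requested shape.
#' Images are interpolated trilinearly; label maps with nearest neighbour so
#' only original label values can appear.
#'
#' @param x (D,H,W) array.
#' @param spacing current (D,H,W) spacing (mm).
#' @param target_spacing desired spacing (mm).
#' @param method `"linear"` for images, `"nearest"` for labels.
#' @param out_shape optional explicit output shape, overriding the rounding
#'   rule (used when inverting a known geometry).
#' @return list `x` (resampled array) and `spacing`.
#' @export
resample_volume <- function(x, spacing, target_spacing,
                            method = c("linear", "nearest"),
                            out_shape = NULL) {
  method <- match.arg(method)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  if (is.null(out_shape)) {
    # round half away from zero (R's round() halves to even)
    raw <- dim(x) * spacing / target_spacing
    out_shape <- pmax(1L, as.integer(floor(raw + 0.5)))
  }
  if (all(out_shape == dim(x)))
    return(list(x = x, spacing = spacing))
  y <- .cpp_resample3d(array(as.double(x), dim(x)), as.integer(out_shape),
                       if (method == "nearest") 1L else 0L)
  if (method == "nearest" && is.integer(x)) {
    y <- array(as.integer(round(y)), out_shape)
  }
  list(x = y, spacing = dim(x) * spacing / out_shape)
}

#' Percentile-clipped z-score normalisation
#'
#' Clips every voxel into the fingerprint window, then subtracts the pooled
#' foreground mean and divides by the pooled foreground standard deviation.
#' Monotone non-decreasing in the input intensity.
#'
#' @param image (D,H,W) array.
#' @param fp a `dataset_fingerprint`.
#' @return normalised array.
#' @export
normalize_volume <- function(image, fp) {
  if (!inherits(fp, "dataset_fingerprint")) stop("fp must be a fingerprint")
  if (fp$fg_std < 1e-8) stop("fingerprint standard deviation too small")
  (pmin(pmax(image, fp$clip_low), fp$clip_high) - fp$fg_mean) / fp$fg_std
}

#' Map a prediction back to the native geometry
#'
#' Label-preserving resample from the preprocessed grid back to the recorded
#' crop-box extent at original spacing, placed into the original shape with
#' background elsewhere.
#'
#' @param pred integer label array in preprocessed (resampled, cropped)
#'   space.
#' @param record the `crop_record` from [crop_to_foreground()].
#' @param fp the fingerprint the prediction space was built with (supplies
#'   the preprocessed spacing).
#' @return integer label array of shape `record$original_shape`.
#' @export
restore_geometry <- function(pred, record, fp) {
  if (!inherits(record, "crop_record")) stop("record must be a crop_record")
  box_shape <- record$box_stop - record$box_start
  if (any(box_shape < 1) || any(record$box_stop > record$original_shape + 1L))
    stop("inconsistent crop record")
  back <- resample_volume(pred, fp$median_spacing, record$spacing,
                          method = "nearest", out_shape = box_shape)$x
  out <- array(0L, record$original_shape)
  out[record$box_start[1]:(record$box_stop[1] - 1L),
      record$box_start[2]:(record$box_stop[2] - 1L),
      record$box_start[3]:(record$box_stop[3] - 1L)] <-
    as.integer(round(back))
  out
}

#' Preprocess one case end to end
#'
#' Crop to foreground, resample image (linear) and label (nearest) to the
#' fingerprint's median spacing, normalise the image.
#'
#' @param case list with `image`, optional `label`, `spacing`.
#' @param fp a `dataset_fingerprint`.
#' @return list `image`, `label`, `spacing`, `record`.
#' @export
preprocess_case <- function(case, fp) {
  cr <- crop_to_foreground(case$image, case$label, case$spacing)
  img <- resample_volume(cr$image, case$spacing, fp$median_spacing,
                         method = "linear")
  lab <- if (!is.null(cr$label))
    resample_volume(cr$label, case$spacing, fp$median_spacing,
                    method = "nearest", out_shape = dim(img$x))$x
  list(image = normalize_volume(img$x, fp), label = lab,
       spacing = fp$median_spacing, record = cr$record)
}
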