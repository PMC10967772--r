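# Synthetic NCCT-like stroke phantoms.
#
# A head is modelled as an ellipsoid of uniform pseudo-HU brightness with a
# mirrored pair of dark ventricle-like ellipsoids, giving the left-right
# symmetric background the symmetry-enhancement features rely on.  One
# hemisphere carries a hypodense penumbra ellipsoid with a more hypodense
# core ellipsoid nested inside (same centre).  The whole scene may be tilted
# in-plane before voxelisation, and seeded Gaussian noise is added last.
# Ground-truth lesion volumes are known analytically (4/3 pi a b c).

#' Phantom parameters
#'
#' All geometric quantities are in millimetres, axis order (D,H,W) with D
#' the axial (thick-slice) axis.  Intensities are float pseudo-HU; the
#' lesion deltas are negative (hypodense) with the core at least as
#' hypodense as the penumbra.
#'
#' @param grid_shape voxels per axis (D,H,W).
#' @param spacing mm per voxel (D,H,W).
#' @param head_axes semi-axes of the head ellipsoid.
#' @param tilt_deg in-plane (H-W) rotation of the whole scene about the
#'   volume centre, in degrees.
#' @param ic_center core/penumbra centre in mm relative to the head centre.
#' @param ic_axes core ellipsoid semi-axes.
#' @param ip_axes penumbra ellipsoid semi-axes (componentwise larger than
#'   `ic_axes`, same centre).
#' @param bg_intensity head tissue intensity.
#' @param ip_delta,ic_delta additive lesion intensities (both negative,
#'   `|ic_delta| >= |ip_delta|`).
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param ventricle_delta additive intensity of the mirrored ventricle pair.
#' @param seed RNG seed used for the noise.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(20L, 160L, 128L),
                           spacing = c(5.0, 0.4, 0.4),
                           head_axes = c(40, 28, 22),
                           tilt_deg = 0,
                           ic_center = c(0, 0, 10),
                           ic_axes = c(7, 5, 4),
                           ip_axes = c(12, 9, 7),
                           bg_intensity = 30,
                           ip_delta = -4,
                           ic_delta = -8,
                           noise_sigma = 1.5,
                           ventricle_delta = -6,
                           seed = 1L) {
  p <- structure(list(grid_shape = as.integer(grid_shape),
                      spacing = as.numeric(spacing),
                      head_axes = as.numeric(head_axes),
                      tilt_deg = as.numeric(tilt_deg),
                      ic_center = as.numeric(ic_center),
                      ic_axes = as.numeric(ic_axes),
                      ip_axes = as.numeric(ip_axes),
                      bg_intensity = as.numeric(bg_intensity),
                      ip_delta = as.numeric(ip_delta),
                      ic_delta = as.numeric(ic_delta),
                      noise_sigma = as.numeric(noise_sigma),
                      ventricle_delta = as.numeric(ventricle_delta),
                      seed = as.integer(seed)),
                 class = "phantom_params")
  validate_phantom_params(p)
  p
}

#' @keywords internal
validate_phantom_params <- function(p) {
  if (any(p$grid_shape <= 0L) || any(p$spacing <= 0))
    stop("grid_shape and spacing must be positive")
  has_lesion <- any(p$ip_axes > 0)
  if (has_lesion) {
    if (!all(p$ip_axes > p$ic_axes))
      stop("ip_axes must exceed ic_axes componentwise")
    if (p$ip_delta > 0 || p$ic_delta > 0)
      stop("lesion deltas must be <= 0")
    if (abs(p$ic_delta) < abs(p$ip_delta))
      stop("|ic_delta| must be >= |ip_delta|")
    # lesion confined to one hemisphere of the head: sample the penumbra
    # surface and require every point inside the head and strictly on one
    # side of the mid-sagittal plane (w = 0)
    th <- seq(0, pi, length.out = 17)
    ph <- seq(0, 2 * pi, length.out = 33)
    pts <- cbind(
      d = p$ic_center[1] + p$ip_axes[1] * rep(cos(th), times = length(ph)),
      h = p$ic_center[2] + p$ip_axes[2] * rep(sin(th), times = length(ph)) *
        rep(cos(ph), each = length(th)),
      w = p$ic_center[3] + p$ip_axes[3] * rep(sin(th), times = length(ph)) *
        rep(sin(ph), each = length(th)))
    inside <- (pts[, 1] / p$head_axes[1])^2 + (pts[, 2] / p$head_axes[2])^2 +
      (pts[, 3] / p$head_axes[3])^2
    if (any(inside > 1))
      stop("lesion leaves the head ellipsoid")
    side <- sign(p$ic_center[3])
    if (side == 0 || any(sign(pts[, 3]) == -side))
      stop("lesion crosses the mid-sagittal plane")
  }
  invisible(TRUE)
}

# physical voxel-centre coordinates relative to the volume centre, after
# undoing the in-plane tilt (rotate sampling grid by -tilt)
.phantom_coords <- function(p) {
  gs <- p$grid_shape; sp <- p$spacing
  cd <- (seq_len(gs[1]) - (gs[1] + 1) / 2) * sp[1]
  ch <- (seq_len(gs[2]) - (gs[2] + 1) / 2) * sp[2]
  cw <- (seq_len(gs[3]) - (gs[3] + 1) / 2) * sp[3]
  d <- array(rep(cd, times = gs[2] * gs[3]), gs)
  h <- array(rep(rep(ch, each = gs[1]), times = gs[3]), gs)
  w <- array(rep(cw, each = gs[1] * gs[2]), gs)
  a <- -p$tilt_deg * pi / 180
  hr <- cos(a) * h - sin(a) * w
  wr <- sin(a) * h + cos(a) * w
  list(d = d, h = hr, w = wr)
}

#' Generate one synthetic stroke phantom
#'
#' @param params a [phantom_params()].
#' @return a list with `image` (D,H,W numeric array), `label` (integer array,
#'   0 background / 1 penumbra / 2 core), `spacing`, and `manifest` with the
#'   analytic penumbra-shell, core and total lesion volumes in mL.
#' @export
generate_phantom <- function(params) {
  p <- params
  validate_phantom_params(p)
  co <- .phantom_coords(p)
  inside <- function(center, axes) {
    if (all(axes <= 0)) return(array(FALSE, p$grid_shape))
    ((co$d - center[1]) / axes[1])^2 + ((co$h - center[2]) / axes[2])^2 +
      ((co$w - center[3]) / axes[3])^2 <= 1
  }
  head <- inside(c(0, 0, 0), p$head_axes)
  img <- array(0, p$grid_shape)
  img[head] <- p$bg_intensity
  # mirrored ventricle-like pair
  vent_axes <- pmin(p$head_axes * c(0.45, 0.28, 0.16), c(20, 9, 4))
  voff <- p$head_axes[3] * 0.22
  img[inside(c(0, 0, voff), vent_axes)] <- p$bg_intensity + p$ventricle_delta
  img[inside(c(0, 0, -voff), vent_axes)] <- p$bg_intensity + p$ventricle_delta
  lab <- array(0L, p$grid_shape)
  has_lesion <- any(p$ip_axes > 0)
  if (has_lesion) {
    ip <- inside(p$ic_center, p$ip_axes)
    ic <- inside(p$ic_center, p$ic_axes)
    img[ip] <- img[ip] + p$ip_delta
    img[ic] <- img[ic] + (p$ic_delta - p$ip_delta)
    lab[ip] <- 1L
    lab[ic] <- 2L
  }
  if (p$noise_sigma > 0) {
    set.seed(p$seed)
    img <- img + array(stats::rnorm(length(img), sd = p$noise_sigma),
                       p$grid_shape)
  }
  vol_ic <- if (has_lesion) 4 / 3 * pi * prod(p$ic_axes) / 1000 else 0
  vol_ip_full <- if (has_lesion) 4 / 3 * pi * prod(p$ip_axes) / 1000 else 0
  list(image = img, label = lab, spacing = p$spacing,
       manifest = c(vol_ip_ml = vol_ip_full - vol_ic,
                    vol_ic_ml = vol_ic,
                    vol_total_ml = vol_ip_full))
}

#' Default parameter ranges for phantom cohorts
#'
#' Uniform sampling ranges: core semi-axis scale (relative to the
#' `phantom_params()` default core axes), penumbra-shell-to-core volume
#' ratio, lesion centre offsets, tilt, intensities and noise.
#'
#' @param ic_scale core size scale range.
#' @param ip_ic_ratio range of the penumbra(label 1)-to-core volume ratio.
#' @param center_h,center_w lesion centre ranges (mm); `center_w` is the
#'   distance from the mid-sagittal plane, with a random side.
#' @param tilt_deg,ip_delta,ic_extra,noise_sigma remaining ranges
#'   (`ic_delta = ip_delta - ic_extra`).
#' @return a list of ranges consumed by [generate_cohort()].
#' @export
phantom_ranges <- function(ic_scale = c(0.65, 1.6),
                           ip_ic_ratio = c(2.0, 5.0),
                           center_h = c(-6, 6),
                           center_w = c(9, 12),
                           tilt_deg = c(-5, 5),
                           ip_delta = c(-5, -3),
                           ic_extra = c(2.5, 5),
                           noise_sigma = c(1.0, 2.0)) {
  r <- list(ic_scale = ic_scale, ip_ic_ratio = ip_ic_ratio,
            center_h = center_h, center_w = center_w, tilt_deg = tilt_deg,
            ip_delta = ip_delta, ic_extra = ic_extra,
            noise_sigma = noise_sigma)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (length(v) != 2L || v[1] > v[2])
      stop("invalid range for ", nm)
  }
  if (r$ip_ic_ratio[1] <= 0) stop("ip_ic_ratio must be positive")
  r
}

#' Generate a phantom cohort
#'
#' Draws `n` parameter sets independently from `ranges` (deterministically
#' given `seed`), generates each phantom and optionally writes NIfTI
#' image/label pairs plus a manifest CSV of the analytic volumes.
#'
#' @param n number of cases.
#' @param ranges a [phantom_ranges()] list.
#' @param seed integer RNG seed.
#' @param out_dir optional directory for `case-XXX.nii.gz`,
#'   `case-XXX_label.nii.gz` and `manifest.csv`.
#' @param base a template [phantom_params()] supplying everything the ranges
#'   do not sample.
#' @return invisible list with `cases` (list of phantoms) and `manifest`
#'   (data frame: case_id, vol_ip_ml, vol_ic_ml, vol_total_ml).
#' @export
generate_cohort <- function(n, ranges = phantom_ranges(), seed = 1L,
                            out_dir = NULL, base = phantom_params()) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  runif2 <- function(r) stats::runif(1, r[1], r[2])
  cases <- vector("list", n)
  man <- vector("list", n)
  for (i in seq_len(n)) {
    p <- NULL
    for (try in seq_len(100L)) {   # rejection-sample geometrically valid draws
      sc <- runif2(ranges$ic_scale)
      ratio <- runif2(ranges$ip_ic_ratio)        # shell / core volume ratio
      side <- sample(c(-1, 1), 1)
      ipd <- runif2(ranges$ip_delta)
      cand <- base
      cand$ic_axes <- base$ic_axes * sc
      cand$ip_axes <- cand$ic_axes * (1 + ratio)^(1 / 3)
      cand$ic_center <- c(0, runif2(ranges$center_h),
                          side * runif2(ranges$center_w))
      cand$tilt_deg <- runif2(ranges$tilt_deg)
      cand$ip_delta <- ipd
      cand$ic_delta <- ipd - runif2(ranges$ic_extra)
      cand$noise_sigma <- runif2(ranges$noise_sigma)
      cand$seed <- sample.int(.Machine$integer.max, 1)
      ok <- tryCatch({ validate_phantom_params(cand); TRUE },
                     error = function(e) FALSE)
      if (ok) { p <- cand; break }
    }
    if (is.null(p)) stop("could not draw a valid phantom from the ranges")
    ph <- generate_phantom(p)
    ph$params <- p
    cases[[i]] <- ph
    man[[i]] <- data.frame(case_id = sprintf("case-%03d", i),
                           t(ph$manifest))
  }
  manifest <- do.call(rbind, man)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      id <- manifest$case_id[i]
      write_nifti(cases[[i]]$image, cases[[i]]$spacing,
                  file.path(out_dir, paste0(id, ".nii.gz")))
      write_nifti(cases[[i]]$label, cases[[i]]$spacing,
                  file.path(out_dir, paste0(id, "_label.nii.gz")),
                  datatype = "uint8")
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  invisible(list(cases = cases, manifest = manifest))
}
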