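# Patch sampling, the augmentation menu and the SGD training loop
# (Nesterov momentum, polynomial learning-rate decay, global gradient-norm
# clipping).

#' Augmentation parameters
#'
#' Per-transform trigger probabilities and magnitude ranges.  Spatial
#' transforms (rotation about the through-plane axis, in-plane scaling,
#' elastic deformation) are composed into a single resampling applied
#' identically to image (bilinear) and label (nearest); intensity transforms
#' touch the image only.  Elastic deformation is available but off by
#' default.
#'
#' @param p_rotation,p_scaling,p_elastic,p_mirror,p_noise,p_blur,p_lowres,p_gamma,p_contrast,p_brightness
#'   trigger probabilities (mirroring is decided per axis).
#' @param rot_deg maximum in-plane rotation (degrees).
#' @param scale_range multiplicative in-plane scale range.
#' @param elastic_alpha,elastic_sigma displacement magnitude (voxels) and
#'   smoothing of the elastic field.
#' @param noise_sigma_range,blur_sigma_range,lowres_factor_range,gamma_range,contrast_range,brightness_range
#'   magnitude ranges of the intensity transforms.
#' @param mirror_axes logical (D,H,W): which axes may be mirrored.
#' @return a list of class `augment_params`.
#' @export
augment_params <- function(p_rotation = 0.2, p_scaling = 0.2, p_elastic = 0,
                           p_mirror = 0.5, p_noise = 0.1, p_blur = 0.2,
                           p_lowres = 0.25, p_gamma = 0.3, p_contrast = 0.15,
                           p_brightness = 0.15,
                           rot_deg = 30, scale_range = c(0.85, 1.15),
                           elastic_alpha = 6, elastic_sigma = 8,
                           noise_sigma_range = c(0, 0.1),
                           blur_sigma_range = c(0.5, 1.0),
                           lowres_factor_range = c(1, 2),
                           gamma_range = c(0.7, 1.5),
                           contrast_range = c(0.75, 1.25),
                           brightness_range = c(-0.1, 0.1),
                           mirror_axes = c(FALSE, TRUE, TRUE)) {
  structure(as.list(environment()), class = "augment_params")
}

#' All-off augmentation (identity)
#' @export
augment_off <- function() {
  augment_params(p_rotation = 0, p_scaling = 0, p_elastic = 0, p_mirror = 0,
                 p_noise = 0, p_blur = 0, p_lowres = 0, p_gamma = 0,
                 p_contrast = 0, p_brightness = 0)
}

#' Training configuration
#'
#' Full-scale defaults follow the training recipe (patch 20 x 320 x 256,
#' batch 2, 300 epochs of 250 iterations, SGD with initial learning rate
#' 1e-2, Nesterov momentum 0.99, weight decay 2e-5, polynomial decay,
#' gradient clipping); [desk_train_config()] scales everything to a single
#' CPU.
#'
#' @param patch_size training patch (D,H,W).
#' @param batch_size patches per optimisation step.
#' @param epochs,iters_per_epoch schedule length.
#' @param lr0 initial learning rate.
#' @param momentum Nesterov momentum coefficient.
#' @param weight_decay L2 weight decay.
#' @param poly_exponent exponent of the polynomial decay.
#' @param grad_clip_norm global gradient-norm bound.
#' @param fg_oversample_fraction fraction of each batch forced to contain a
#'   foreground voxel (when the case has any): `ceil(fraction * batch_size)`
#'   patches per batch are lesion-centred, so every optimisation step sees
#'   foreground even at batch size 1.
#' @param augment an [augment_params()] list.
#' @param seed RNG seed for sampling, augmentation and initialisation.
#' @return a list of class `train_config`.
#' @export
train_config <- function(patch_size = c(20L, 320L, 256L), batch_size = 2L,
                         epochs = 300L, iters_per_epoch = 250L,
                         lr0 = 1e-2, momentum = 0.99, weight_decay = 2e-5,
                         poly_exponent = 0.9, grad_clip_norm = 12,
                         fg_oversample_fraction = 1 / 3,
                         augment = augment_params(), seed = 1L) {
  if (lr0 < 0 || momentum < 0 || weight_decay < 0)
    stop("rates must be non-negative")
  structure(list(patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 iters_per_epoch = as.integer(iters_per_epoch),
                 lr0 = lr0, momentum = momentum,
                 weight_decay = weight_decay,
                 poly_exponent = poly_exponent,
                 grad_clip_norm = grad_clip_norm,
                 fg_oversample_fraction = fg_oversample_fraction,
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training configuration (single CPU)
#'
#' Besides the reduced patch, batch and schedule, the desk default lowers
#' the Nesterov momentum to 0.95: the full-scale momentum of 0.99 is
#' calibrated for millions of voxels per optimisation step, and with a
#' single 16 x 64 x 64 patch per step the gradient noise it amplifies can
#' keep short schedules from ever leaving the all-background regime.
#'
#' @param ... overrides passed to [train_config()].
#' @export
desk_train_config <- function(...) {
  defaults <- list(patch_size = c(16L, 64L, 64L), batch_size = 1L,
                   epochs = 12L, iters_per_epoch = 50L, momentum = 0.95)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

#' Polynomial learning-rate schedule
#'
#' `lr = lr0 * (1 - epoch/epochs)^exponent`.
#'
#' @param epoch current epoch (0-based, `0 <= epoch <= epochs`).
#' @param cfg a [train_config()].
#' @return learning rate.
#' @export
poly_lr <- function(epoch, cfg) {
  if (epoch < 0 || epoch > cfg$epochs) stop("epoch out of range")
  cfg$lr0 * (1 - epoch / cfg$epochs)^cfg$poly_exponent
}

# pad (D,H,W) array to at least `shape`, symmetric, constant fill
.pad_to <- function(x, shape, fill) {
  d <- dim(x)
  if (all(d >= shape)) return(list(x = x, lo = c(0L, 0L, 0L)))
  need <- pmax(shape - d, 0L)
  lo <- need %/% 2L
  out <- array(fill, pmax(d, shape))
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- x
  list(x = out, lo = lo)
}

#' Sample a training patch
#'
#' Uniform random window; with probability `fg_prob` the window is forced to
#' contain at least one foreground voxel when the case has any.  Cases
#' smaller than the patch are symmetrically padded (image with its minimum,
#' label with background).
#'
#' @param image,label preprocessed case arrays.
#' @param patch_size (D,H,W).
#' @param fg_prob foreground-oversampling probability.
#' @param fg_index optional precomputed `which(label > 0, arr.ind = TRUE)`
#'   (in unpadded coordinates) to avoid a full scan per draw.
#' @return list `image`, `label` of the patch size.
#' @export
sample_patch <- function(image, label, patch_size, fg_prob = 1 / 3,
                         fg_index = NULL) {
  pim <- .pad_to(image, patch_size, min(image))
  pla <- .pad_to(label, patch_size, 0L)
  img <- pim$x; lab <- pla$x
  shp <- dim(img)
  if (is.null(fg_index)) fg_index <- which(label > 0L, arr.ind = TRUE)
  force_fg <- stats::runif(1) < fg_prob && nrow(fg_index) > 0L
  if (force_fg) {
    v <- fg_index[sample.int(nrow(fg_index), 1L), ] + pla$lo
    start <- integer(3)
    for (a in 1:3) {
      lo <- max(1L, v[a] - patch_size[a] + 1L)
      hi <- min(shp[a] - patch_size[a] + 1L, v[a])
      start[a] <- if (hi <= lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    }
  } else {
    start <- vapply(1:3, function(a) {
      r <- shp[a] - patch_size[a] + 1L
      sample.int(r, 1L)
    }, integer(1))
  }
  sel <- lapply(1:3, function(a) start[a] + seq_len(patch_size[a]) - 1L)
  list(image = img[sel[[1]], sel[[2]], sel[[3]], drop = FALSE],
       label = lab[sel[[1]], sel[[2]], sel[[3]], drop = FALSE])
}

# separable in-plane Gaussian blur of a (D,H,W) array
.blur_inplane <- function(x, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  d5 <- array(x, c(dim(x), 1L, 1L))
  kh <- array(k, c(1L, 2L * r + 1L, 1L, 1L))
  kw <- array(k, c(1L, 1L, 2L * r + 1L, 1L))
  y <- .cpp_dwconv3d_fwd(d5, kh, NULL, c(0L, r, 0L))
  y <- .cpp_dwconv3d_fwd(y, kw, NULL, c(0L, 0L, r))
  array(y, dim(x))
}

#' Apply the augmentation menu to one patch pair
#'
#' @param image,label aligned (D,H,W) patch pair.
#' @param params an [augment_params()] list; each transform fires with its
#'   own probability using the current RNG state.
#' @return list `image`, `label`, shapes unchanged.
#' @export
augment_patch <- function(image, label, params = augment_params()) {
  stopifnot(all(dim(image) == dim(label)))
  p <- params
  fill <- min(image)
  # ---- spatial: one combined in-plane warp
  do_rot <- stats::runif(1) < p$p_rotation
  do_scl <- stats::runif(1) < p$p_scaling
  do_ela <- stats::runif(1) < p$p_elastic
  if (do_rot || do_scl || do_ela) {
    theta <- if (do_rot) stats::runif(1, -p$rot_deg, p$rot_deg) * pi / 180 else 0
    sc <- if (do_scl) stats::runif(1, p$scale_range[1], p$scale_range[2]) else 1
    # source = R(theta)/scale applied to target coords (inverse mapping)
    A <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)),
                2, 2, byrow = TRUE) / sc
    dh <- dw <- NULL
    if (do_ela) {
      dh <- .blur_inplane(array(stats::rnorm(length(image)), dim(image)),
                          p$elastic_sigma) * p$elastic_alpha * p$elastic_sigma
      dw <- .blur_inplane(array(stats::rnorm(length(image)), dim(image)),
                          p$elastic_sigma) * p$elastic_alpha * p$elastic_sigma
    }
    image <- .cpp_warp_inplane(image, as.numeric(t(A)), c(0, 0),
                               dh, dw, 0L, fill)
    label <- array(as.integer(round(.cpp_warp_inplane(
      array(as.double(label), dim(label)), as.numeric(t(A)), c(0, 0),
      dh, dw, 1L, 0))), dim(label))
  }
  # ---- mirroring, per enabled axis
  for (a in 1:3) {
    if (p$mirror_axes[a] && stats::runif(1) < p$p_mirror) {
      idx <- rev(seq_len(dim(image)[a]))
      if (a == 1L) { image <- image[idx, , , drop = FALSE]; label <- label[idx, , , drop = FALSE] }
      if (a == 2L) { image <- image[, idx, , drop = FALSE]; label <- label[, idx, , drop = FALSE] }
      if (a == 3L) { image <- image[, , idx, drop = FALSE]; label <- label[, , idx, drop = FALSE] }
    }
  }
  # ---- intensity (image only)
  if (stats::runif(1) < p$p_noise) {
    s <- stats::runif(1, p$noise_sigma_range[1], p$noise_sigma_range[2])
    image <- image + array(stats::rnorm(length(image), sd = s), dim(image))
  }
  if (stats::runif(1) < p$p_blur) {
    s <- stats::runif(1, p$blur_sigma_range[1], p$blur_sigma_range[2])
    image <- .blur_inplane(image, s)
  }
  if (stats::runif(1) < p$p_lowres) {
    f <- stats::runif(1, p$lowres_factor_range[1], p$lowres_factor_range[2])
    small <- pmax(1L, as.integer(round(dim(image) / c(1, f, f))))
    ds <- .cpp_resample3d(image, small, 0L)
    image <- .cpp_resample3d(ds, dim(label), 0L)
  }
  if (stats::runif(1) < p$p_gamma) {
    g <- stats::runif(1, p$gamma_range[1], p$gamma_range[2])
    rng <- range(image)
    if (diff(rng) > 1e-8)
      image <- ((image - rng[1]) / diff(rng))^g * diff(rng) + rng[1]
  }
  if (stats::runif(1) < p$p_contrast) {
    f <- stats::runif(1, p$contrast_range[1], p$contrast_range[2])
    m <- mean(image)
    image <- (image - m) * f + m
  }
  if (stats::runif(1) < p$p_brightness) {
    image <- image + stats::runif(1, p$brightness_range[1],
                                  p$brightness_range[2])
  }
  list(image = image, label = label)
}

# global-norm gradient clipping over a flat list of parameter nodes;
# returns the pre-clip norm
.clip_grads <- function(params, max_norm) {
  sq <- 0
  for (pn in params) if (!is.null(pn$grad)) sq <- sq + sum(pn$grad^2)
  nrm <- sqrt(sq)
  if (is.finite(max_norm) && nrm > max_norm && nrm > 0) {
    sc <- max_norm / nrm
    for (pn in params) if (!is.null(pn$grad)) pn$grad <- pn$grad * sc
  }
  nrm
}

# one SGD step with Nesterov momentum and weight decay; `state` is a list of
# momentum buffers aligned with `params`
.sgd_step <- function(params, state, lr, momentum, weight_decay,
                      nesterov = TRUE) {
  for (i in seq_along(params)) {
    pn <- params[[i]]
    if (is.null(pn$grad)) next
    g <- pn$grad + weight_decay * pn$value
    v <- state[[i]]
    if (is.null(v)) v <- 0
    v <- momentum * v + g
    step <- if (nesterov) g + momentum * v else v
    pn$value <- pn$value - lr * step
    state[[i]] <- v
  }
  state
}

#' Train the segmentation network
#'
#' Runs `epochs * iters_per_epoch` SGD steps of the hierarchical
#' deep-supervision loss on randomly sampled, augmented patches.
#' Deterministic given `tcfg$seed` (up to floating-point non-associativity).
#'
#' @param cases list of preprocessed cases (`image`, `label`, `spacing`).
#' @param cfg an [arch_config()].
#' @param tcfg a [train_config()].
#' @param scheme a [supervision_scheme()]; defaults to one matching `cfg`.
#' @param init optional initial weights (checkpoint) to continue from.
#' @param verbose print per-epoch mean loss.
#' @return list with `weights` (plain arrays), `loss_log` (data frame:
#'   epoch, iter, lr, loss, grad_norm) and the configurations.
#' @export
train_loop <- function(cases, cfg, tcfg, scheme = NULL, init = NULL,
                       verbose = FALSE) {
  if (length(cases) < 1) stop("at least one training case is required")
  check_patch(cfg, tcfg$patch_size)
  n_dec <- cfg$n_levels - 1L
  if (is.null(scheme))
    scheme <- supervision_scheme(n_levels = n_dec,
                                 classes_per_level = cfg$head_classes)
  if (!all(scheme$classes_per_level == cfg$head_classes))
    stop("scheme class counts disagree with the architecture heads")
  set.seed(tcfg$seed)
  fg_indices <- lapply(cases, function(cs) which(cs$label > 0L, arr.ind = TRUE))
  weights <- if (is.null(init)) network_init(cfg) else init
  nodes <- params_to_nodes(weights)
  flat <- flatten_params(nodes)
  state <- vector("list", length(flat))
  shapes <- head_shapes(cfg, tcfg$patch_size)
  log_rows <- vector("list", tcfg$epochs * tcfg$iters_per_epoch)
  r <- 0L
  for (ep in seq_len(tcfg$epochs)) {
    lr <- poly_lr(ep - 1L, tcfg)
    for (it in seq_len(tcfg$iters_per_epoch)) {
      B <- tcfg$batch_size
      xb <- array(0, c(tcfg$patch_size, 1L, B))
      lb <- array(0L, c(tcfg$patch_size, B))
      # foreground guarantee: ceil(fraction * B) slots of every batch are
      # lesion-centred; any fractional remainder is scheduled as a regular
      # cadence over steps (e.g. fraction 1/3 at batch 1 forces every third
      # step), so lesion exposure never suffers random streaks
      frac <- tcfg$fg_oversample_fraction * B
      n_forced <- floor(frac + 1e-9)
      rem <- frac - n_forced
      if (rem > 1e-9) {
        period <- round(1 / rem)
        step <- (ep - 1L) * tcfg$iters_per_epoch + it
        if (step %% period == 1L %% period) n_forced <- n_forced + 1L
      }
      for (b in seq_len(B)) {
        ci <- sample.int(length(cases), 1L)
        cs <- cases[[ci]]
        pt <- sample_patch(cs$image, cs$label, tcfg$patch_size,
                           if (b <= n_forced) 1 else 0, fg_indices[[ci]])
        pt <- augment_patch(pt$image, pt$label, tcfg$augment)
        xb[, , , 1L, b] <- pt$image
        lb[, , , b] <- pt$label
      }
      targets <- downsample_labels(lb, shapes, scheme$classes_per_level)
      ag_zero_grad(flat)
      logits <- network_forward(xb, cfg, nodes)
      loss <- hierarchical_total_loss(logits, targets, scheme)
      if (!is.finite(ag_value(loss)))
        stop("non-finite loss at epoch ", ep, ", iteration ", it)
      ag_backward(loss)
      gn <- .clip_grads(flat, tcfg$grad_clip_norm)
      state <- .sgd_step(flat, state, lr, tcfg$momentum, tcfg$weight_decay)
      r <- r + 1L
      log_rows[[r]] <- data.frame(epoch = ep, iter = it, lr = lr,
                                  loss = ag_value(loss), grad_norm = gn)
    }
    if (verbose) {
      ep_loss <- mean(vapply(log_rows[(r - tcfg$iters_per_epoch + 1L):r],
                             function(x) x$loss, numeric(1)))
      message(sprintf("epoch %d/%d  lr %.2e  loss %.4f",
                      ep, tcfg$epochs, lr, ep_loss))
    }
  }
  list(weights = params_to_arrays(nodes),
       loss_log = do.call(rbind, log_rows[seq_len(r)]),
       arch = cfg, train = tcfg, scheme = scheme)
}
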