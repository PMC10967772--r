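# Deep-supervision losses.  Each decoder level is scored with a compound
# Dice + cross-entropy loss against a nearest-neighbour downsampled label
# pyramid; deep levels see the binary problem (background vs whole lesion),
# shallow levels the 3-class problem, and the per-level losses are combined
# with fixed weights.

#' Deep-supervision scheme
#'
#' @param n_levels number of decoder levels (default 6).
#' @param res_weights per-level weights, deepest first.  The 6-level default
#'   is `c(0.02, 0.08, 0.2, 0.1, 0.2, 0.4)` (summing to 1); for other depths
#'   weights proportional to `2^(i-1)` (deepest smallest), normalised to 1.
#' @param alpha,beta coefficients of the Dice and cross-entropy terms.
#' @param classes_per_level per-level class counts, deepest first; default
#'   2 for the deeper half, 3 for the rest.
#' @param ce_mode at 3-class levels the per-region loss sum `L_IP + L_IC`
#'   uses per-foreground-class Dice terms plus either one shared 3-class
#'   cross-entropy (`"shared"`, default) or the cross-entropy counted once
#'   per region (`"per_class"`).
#' @return an object of class `supervision_scheme`.
#' @export
supervision_scheme <- function(n_levels = 6L, res_weights = NULL,
                               alpha = 1, beta = 1,
                               classes_per_level = NULL,
                               ce_mode = c("shared", "per_class")) {
  n_levels <- as.integer(n_levels)
  ce_mode <- match.arg(ce_mode)
  if (is.null(res_weights)) {
    res_weights <- if (n_levels == 6L) c(0.02, 0.08, 0.2, 0.1, 0.2, 0.4)
    else 2^(seq_len(n_levels) - 1) / sum(2^(seq_len(n_levels) - 1))
  }
  if (length(res_weights) != n_levels || any(res_weights < 0))
    stop("res_weights must be non-negative, one per decoder level")
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  if (is.null(classes_per_level)) {
    n2 <- n_levels %/% 2L
    classes_per_level <- c(rep(2L, n2), rep(3L, n_levels - n2))
  }
  if (length(classes_per_level) != n_levels)
    stop("classes_per_level must have one entry per decoder level")
  structure(list(n_levels = n_levels, res_weights = res_weights,
                 alpha = alpha, beta = beta,
                 classes_per_level = as.integer(classes_per_level),
                 ce_mode = ce_mode),
            class = "supervision_scheme")
}

#' Grids of the decoder heads, deepest first
#' @param cfg an [arch_config()].
#' @param patch (D,H,W) patch size.
#' @return `(n_levels - 1) x 3` matrix.
#' @export
head_shapes <- function(cfg, patch) {
  shp <- level_shapes(cfg, patch)
  shp[rev(seq_len(cfg$n_levels - 1L)), , drop = FALSE]
}

#' Build the label pyramid for deep supervision
#'
#' Nearest-neighbour (label-preserving) downsampling of the ground-truth map
#' to each decoder grid; at 2-class levels the penumbra and core labels are
#' merged into a single foreground label.
#'
#' @param label integer array (D,H,W) or (D,H,W,B) over `{0,1,2}`.
#' @param shapes per-level (D,H,W) grids, deepest first ([head_shapes()]).
#' @param classes_per_level per-level class counts, deepest first.
#' @return list of integer label arrays (D,H,W,B), deepest first.
#' @export
downsample_labels <- function(label, shapes, classes_per_level) {
  if (length(dim(label)) == 3L) dim(label) <- c(dim(label), 1L)
  if (nrow(shapes) != length(classes_per_level))
    stop("one class count per level is required")
  B <- dim(label)[4]
  lapply(seq_len(nrow(shapes)), function(i) {
    out <- array(0L, c(as.integer(shapes[i, ]), B))
    for (b in seq_len(B)) {
      ds <- .cpp_resample3d(array(as.double(label[, , , b]), dim(label)[1:3]),
                            as.integer(shapes[i, ]), 1L)
      out[, , , b] <- as.integer(round(ds))
    }
    if (classes_per_level[i] == 2L) out[out > 1L] <- 1L
    out
  })
}

# softmax over the class axis of an (nsp, K) matrix
.softmax_rows <- function(z) {
  mx <- z[, 1]
  for (k in seq_len(ncol(z))[-1]) mx <- pmax(mx, z[, k])
  ez <- exp(z - mx)
  ez / rowSums(ez)
}

# Compound Dice + cross-entropy with analytic gradient.
# fg_reduce: "mean" averages the Dice loss over foreground classes,
# "sum" adds one full Dice loss per foreground class (the per-region form
# used at 3-class deep-supervision levels).
.seg_loss <- function(logits, target, alpha = 1, beta = 1,
                      fg_reduce = "mean", eps = 1e-5) {
  zv <- ag_value(logits)
  dm <- dim(zv)
  K <- dm[4]; B <- dm[5]
  nsp <- prod(dm[1:3])
  if (length(dim(target)) == 3L) dim(target) <- c(dim(target), 1L)
  if (!all(dim(target) == c(dm[1:3], B))) stop("target shape mismatch")
  tv <- as.integer(target)
  if (any(tv < 0L | tv >= K)) stop("target values must be < class count")
  fg <- seq_len(K - 1L)          # foreground class indices (0-based: 1..K-1)
  nfg <- length(fg)
  val_ce <- 0; val_dice <- 0
  grad_z <- array(0, dm)
  for (b in seq_len(B)) {
    z <- matrix(zv[, , , , b], nsp, K)
    p <- .softmax_rows(z)
    tb <- tv[(b - 1L) * nsp + seq_len(nsp)]
    g <- matrix(0, nsp, K)
    g[cbind(seq_len(nsp), tb + 1L)] <- 1
    val_ce <- val_ce - sum(log(pmax(p[cbind(seq_len(nsp), tb + 1L)], 1e-12))) / (nsp * B)
    dLdp <- matrix(0, nsp, K)
    dLdp <- dLdp + (-(g / pmax(p, 1e-12))) * (beta / (nsp * B))
    for (cc in fg) {
      k <- cc + 1L
      Spg <- sum(p[, k] * g[, k]); Sp <- sum(p[, k]); Sg <- sum(g[, k])
      den <- Sp + Sg + eps
      dice <- (2 * Spg + eps) / den
      share <- if (fg_reduce == "mean") 1 / (nfg * B) else 1 / B
      val_dice <- val_dice + (1 - dice) * share
      # d(1-dice)/dp_k = -(2 g den - (2 Spg + eps)) / den^2
      dLdp[, k] <- dLdp[, k] -
        alpha * share * (2 * g[, k] * den - (2 * Spg + eps)) / den^2
    }
    # chain through softmax: dL/dz_k = p_k (dL/dp_k - sum_j dL/dp_j p_j)
    dot <- rowSums(dLdp * p)
    gz <- p * (dLdp - dot)
    grad_z[, , , , b] <- gz
  }
  value <- alpha * val_dice + beta * val_ce
  if (!is_node(logits)) return(value)
  ag_node(value, parents = list(logits),
          backward = function(gy) list(gy * grad_z))
}

#' Compound Dice + cross-entropy loss
#'
#' `alpha * L_Dice + beta * L_CE` where the Dice loss is one minus the
#' smoothed soft Dice averaged over the foreground classes (background
#' excluded), computed per sample and averaged over the batch, and the
#' cross-entropy is the voxelwise mean over all classes.
#'
#' @param logits tensor (D,H,W,K,B), plain array or tape node.
#' @param target integer array (D,H,W) or (D,H,W,B) with values `< K`.
#' @param alpha,beta term coefficients.
#' @param eps Dice smoothing added to numerator and denominator.
#' @return scalar (or scalar node when `logits` is taped), always >= 0.
#' @export
compound_loss <- function(logits, target, alpha = 1, beta = 1, eps = 1e-5) {
  .seg_loss(logits, target, alpha, beta, fg_reduce = "mean", eps = eps)
}

#' Combine per-level named loss terms with the supervision weights
#'
#' At 2-class levels the single compound loss is weighted by `Res_i`; at
#' 3-class levels the penumbra and core region losses are summed first.
#' Exposed separately so the weighting arithmetic can be exercised without a
#' network.
#'
#' @param scheme a [supervision_scheme()].
#' @param terms list, deepest first: a scalar at 2-class levels, a length-2
#'   vector `(L_IP, L_IC)` at 3-class levels.
#' @return the weighted total.
#' @export
supervision_total <- function(scheme, terms) {
  stopifnot(length(terms) == scheme$n_levels)
  tot <- 0
  for (i in seq_len(scheme$n_levels)) {
    ti <- terms[[i]]
    expected <- if (scheme$classes_per_level[i] == 2L) 1L else 2L
    if (length(ti) != expected) stop("level ", i, ": wrong number of terms")
    tot <- tot + scheme$res_weights[i] * sum(ti)
  }
  tot
}

#' Hierarchical deep-supervision total loss
#'
#' Deep (2-class) levels contribute `Res_i * L(2-class)`; shallow (3-class)
#' levels contribute `Res_i * (L_IP + L_IC)`, realised as one full Dice loss
#' per foreground region plus the shared 3-class cross-entropy (counted once
#' by default, or once per region with `ce_mode = "per_class"`).
#'
#' @param logits_list per-level logits, deepest first ([network_forward()]).
#' @param target_list matching label pyramid ([downsample_labels()]).
#' @param scheme a [supervision_scheme()].
#' @return scalar loss (a tape node when the logits are taped).
#' @export
hierarchical_total_loss <- function(logits_list, target_list, scheme) {
  n <- scheme$n_levels
  if (length(logits_list) != n || length(target_list) != n)
    stop("logits/target lists must match the scheme's level count")
  vals <- vector("list", n)
  for (i in seq_len(n)) {
    K <- dim(ag_value(logits_list[[i]]))[4]
    if (K != scheme$classes_per_level[i])
      stop("level ", i, ": logits have ", K, " classes, scheme expects ",
           scheme$classes_per_level[i])
    if (K == 2L) {
      vals[[i]] <- .seg_loss(logits_list[[i]], target_list[[i]],
                             scheme$alpha, scheme$beta, fg_reduce = "mean")
    } else {
      beta_eff <- if (scheme$ce_mode == "per_class") 2 * scheme$beta else scheme$beta
      vals[[i]] <- .seg_loss(logits_list[[i]], target_list[[i]],
                             scheme$alpha, beta_eff, fg_reduce = "sum")
    }
  }
  taped <- vapply(vals, is_node, logical(1))
  total_val <- sum(scheme$res_weights * vapply(vals, ag_value, numeric(1)))
  if (!any(taped)) return(total_val)
  ag_node(total_val, parents = vals, backward = function(gy) {
    lapply(seq_len(n), function(i) gy * scheme$res_weights[i])
  })
}
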