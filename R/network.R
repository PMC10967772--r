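# The segmentation network: a U-shaped 3-D encoder-decoder.  The encoder
# stacks multi-scale depthwise convolution (MSC) blocks, with a symmetry
# enhancement (SE) block appended at the deep levels; the decoder is
# attention-gated with transposed-convolution upsampling and one
# 1x1x1 segmentation head per level for deep supervision.
#
# Feature arrays are stored (D,H,W,C,B) with D fastest; shapes are quoted
# as (B,C,D,H,W) in the documentation.

#' Architecture configuration
#'
#' Describes the encoder-decoder: number of levels, per-level channel
#' counts, the large-kernel set of the MSC blocks, which deep levels carry a
#' symmetry-enhancement block, and the anisotropic stride schedule.  In-plane
#' axes (H, W) are downsampled by 2 at every level transition; the
#' through-plane axis D is downsampled only at the last `n_d_strides`
#' transitions, matching thick-slice CT where D has far fewer voxels.
#'
#' @param n_levels encoder depth (the decoder has `n_levels - 1` levels).
#' @param channels integer vector of per-level feature channels
#'   (length `n_levels`).
#' @param msc_kernels large in-plane kernel sizes of the MSC branches.
#' @param se_levels encoder levels carrying an SE block; default the deepest
#'   four (or all but the shallowest when fewer than five levels).
#' @param n_d_strides number of level transitions at which the D axis is
#'   strided (default 2).
#' @param flip_axis spatial axis mirrored by the SE block: 1 = D, 2 = H,
#'   3 = W (default W, the left-right axis).
#' @param head_classes class count of each decoder head, deepest first;
#'   default: the deeper half predict 2 classes (background vs whole lesion),
#'   the shallower half 3 classes (background / penumbra / core).
#' @param ref_patch reference training patch size (D,H,W); used to clip
#'   through-plane kernel extents at deep levels where D is small.
#' @param in_channels input image channels (1 for NCCT).
#' @return an object of class `arch_config`.
#' @export
arch_config <- function(n_levels = 7L,
                        channels = c(32L, 64L, 128L, 256L, 320L, 320L, 320L),
                        msc_kernels = c(5L, 7L, 11L),
                        se_levels = NULL,
                        n_d_strides = 2L,
                        flip_axis = 3L,
                        head_classes = NULL,
                        ref_patch = c(20L, 320L, 256L),
                        in_channels = 1L) {
  n_levels <- as.integer(n_levels)
  if (length(channels) != n_levels)
    stop("`channels` must have one entry per level")
  if (is.null(se_levels)) {
    k <- min(4L, n_levels - 1L)
    se_levels <- seq.int(n_levels - k + 1L, n_levels)
  }
  n_dec <- n_levels - 1L
  if (is.null(head_classes)) {
    n2 <- n_dec %/% 2L
    head_classes <- c(rep(2L, n2), rep(3L, n_dec - n2))
  }
  if (length(head_classes) != n_dec)
    stop("`head_classes` must have one entry per decoder level")
  cfg <- structure(list(
    n_levels = n_levels,
    channels = as.integer(channels),
    msc_kernels = as.integer(msc_kernels),
    se_levels = as.integer(se_levels),
    n_d_strides = as.integer(n_d_strides),
    flip_axis = as.integer(flip_axis),
    head_classes = as.integer(head_classes),
    ref_patch = as.integer(ref_patch),
    in_channels = as.integer(in_channels)
  ), class = "arch_config")
  cfg
}

#' Per-transition stride schedule
#'
#' @param cfg an [arch_config()].
#' @return a `(n_levels - 1) x 3` matrix of (D,H,W) strides, transition t
#'   entering level t + 1.
#' @export
stride_schedule <- function(cfg) {
  nt <- cfg$n_levels - 1L
  s <- matrix(2L, nt, 3)
  d1 <- nt - cfg$n_d_strides
  if (d1 > 0) s[seq_len(d1), 1] <- 1L
  colnames(s) <- c("D", "H", "W")
  s
}

#' Spatial grid of every encoder level for a given patch size
#'
#' @param cfg an [arch_config()].
#' @param patch integer (D,H,W) patch size.
#' @return an `n_levels x 3` matrix of per-level grids.
#' @export
level_shapes <- function(cfg, patch) {
  check_patch(cfg, patch)
  s <- stride_schedule(cfg)
  out <- matrix(0L, cfg$n_levels, 3)
  out[1, ] <- as.integer(patch)
  for (t in seq_len(cfg$n_levels - 1L))
    out[t + 1L, ] <- out[t, ] %/% s[t, ]
  colnames(out) <- c("D", "H", "W")
  out
}

#' Validate a patch size against the stride schedule
#' @param cfg an [arch_config()].
#' @param patch integer (D,H,W).
#' @return invisibly `TRUE`; stops naming the offending axes otherwise.
#' @export
check_patch <- function(cfg, patch) {
  patch <- as.integer(patch)
  need <- c(2L^cfg$n_d_strides, 2L^(cfg$n_levels - 1L), 2L^(cfg$n_levels - 1L))
  bad <- which(patch %% need != 0L)
  if (length(bad))
    stop("patch axes ", paste(c("D", "H", "W")[bad], collapse = ", "),
         " must be divisible by ", paste(need[bad], collapse = ", "))
  invisible(TRUE)
}

# largest odd extent <= min(k, d), at least 1
.clip_odd <- function(k, d) {
  k <- min(k, d)
  if (k %% 2L == 0L) k <- k - 1L
  max(1L, k)
}

.init_conv <- function(kd, kh, kw, cin, cout, slope = 0.01) {
  fan_in <- kd * kh * kw * cin
  sd <- sqrt(2 / ((1 + slope^2) * fan_in))
  list(w = array(stats::rnorm(kd * kh * kw * cin * cout, sd = sd),
                 c(kd, kh, kw, cin, cout)),
       b = numeric(cout))
}

.init_dw <- function(kd, kh, kw, c) {
  fan_in <- kd * kh * kw
  sd <- sqrt(2 / fan_in)
  list(w = array(stats::rnorm(kd * kh * kw * c, sd = sd), c(kd, kh, kw, c)),
       b = numeric(c))
}

.init_convt <- function(cin, cout, s) {
  fan_in <- cin * prod(s)
  sd <- sqrt(2 / fan_in)
  list(w = array(stats::rnorm(cin * cout * prod(s), sd = sd),
                 c(cin, cout, s[1], s[2], s[3])),
       b = numeric(cout))
}

.init_norm <- function(c) list(gamma = rep(1, c), beta = numeric(c))

.init_msc <- function(cin, cout, kernels, d_ref) {
  scales <- lapply(kernels, function(k) {
    kd <- .clip_odd(k, d_ref)
    list(inplane = .init_dw(1L, k, k, cout),
         throughplane = .init_dw(kd, 1L, 1L, cout))
  })
  list(conv = c(.init_conv(3L, 3L, 3L, cin, cout), .init_norm(cout)),
       dw3 = .init_dw(.clip_odd(3L, d_ref), 3L, 3L, cout),
       scales = scales,
       fuse = c(.init_conv(1L, 1L, 1L, cout, cout), .init_norm(cout)))
}

#' Initialise network weights
#'
#' He-style initialisation scaled for leaky-ReLU; instance-norm affine
#' parameters start at identity.  Deterministic given the R RNG state.
#'
#' @param cfg an [arch_config()].
#' @param seed optional integer seed.
#' @return a nested list of numeric arrays (the checkpoint format).
#' @export
network_init <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- cfg$channels
  L <- cfg$n_levels
  s <- stride_schedule(cfg)
  shp <- level_shapes(cfg, cfg$ref_patch)
  enc <- vector("list", L)
  stem <- c(.init_conv(3L, 3L, 3L, cfg$in_channels, ch[1]), .init_norm(ch[1]))
  for (l in seq_len(L)) {
    lev <- list()
    if (l > 1L)
      lev$down <- c(.init_conv(3L, 3L, 3L, ch[l - 1L], ch[l]), .init_norm(ch[l]))
    lev$msc <- .init_msc(if (l == 1L) ch[1] else ch[l], ch[l],
                         cfg$msc_kernels, shp[l, 1])
    if (l %in% cfg$se_levels)
      lev$se <- c(.init_conv(1L, 1L, 1L, 2L * ch[l], ch[l]), .init_norm(ch[l]))
    enc[[l]] <- lev
  }
  dec <- vector("list", L - 1L)
  for (i in seq_len(L - 1L)) {       # i = 1 deepest
    l <- L - i                       # target encoder level
    cint <- max(1L, ch[l] %/% 2L)
    dec[[i]] <- list(
      up = .init_convt(ch[l + 1L], ch[l], s[l, ]),
      gate = list(wg = .init_conv(1L, 1L, 1L, ch[l], cint),
                  wx = .init_conv(1L, 1L, 1L, ch[l], cint),
                  psi = .init_conv(1L, 1L, 1L, cint, 1L)),
      fuse = c(.init_conv(3L, 3L, 3L, 2L * ch[l], ch[l]), .init_norm(ch[l])),
      head = .init_conv(1L, 1L, 1L, ch[l], cfg$head_classes[i])
    )
  }
  list(stem = stem, encoder = enc, decoder = dec)
}

# conv + instance norm + leaky relu
.cna <- function(x, p, stride = c(1L, 1L, 1L), slope = 0.01) {
  op_leaky_relu(op_instancenorm(op_conv3d(x, p$w, p$b, stride = stride),
                                p$gamma, p$beta), slope)
}

#' Multi-scale convolution block forward
#'
#' A 3x3x3 convolution block (conv + instance norm + leaky ReLU) whose output
#' feeds a 3x3x3 depthwise convolution followed by parallel decomposed
#' depthwise branches (1 x k x k then k x 1 x 1, no normalisation or
#' activation) plus an identity branch; the branch sum passes through a
#' 1x1x1 fusion convolution block, and the first convolution's output is added
#' back as a residual.
#'
#' @param x input tensor (plain array or tape node), stored (D,H,W,C,B).
#' @param p block weights (one entry of `network_init()$encoder[[l]]$msc`).
#' @param slope leaky-ReLU negative slope.
#' @return output tensor, same spatial shape, the block's channel count.
#' @export
msc_block_forward <- function(x, p, slope = 0.01) {
  xp <- .cna(x, p$conv, slope = slope)
  u <- op_dwconv3d(xp, p$dw3$w, p$dw3$b)
  s <- u
  for (sc in p$scales) {
    v <- op_dwconv3d(u, sc$inplane$w, sc$inplane$b)
    v <- op_dwconv3d(v, sc$throughplane$w, sc$throughplane$b)
    s <- op_add(s, v)
  }
  op_add(.cna(s, p$fuse, slope = slope), xp)
}

#' Symmetry enhancement block forward
#'
#' Mirrors the feature map along the left-right axis, subtracts the mirrored
#' copy from the original, concatenates the difference with the input along
#' channels, fuses with a 1x1x1 convolution block and adds the input back.
#' For a perfectly mirror-symmetric activation the difference operand is
#' identically zero, so the block degenerates to a learned residual update
#' driven by the input alone.
#'
#' @param x input tensor.
#' @param p SE block weights (`w`, `b`, `gamma`, `beta`).
#' @param flip_axis spatial axis to mirror (1 = D, 2 = H, 3 = W).
#' @param slope leaky-ReLU negative slope.
#' @return output tensor, same shape as the input.
#' @export
se_block_forward <- function(x, p, flip_axis = 3L, slope = 0.01) {
  dif <- op_sub(x, op_flip(x, flip_axis))
  op_add(.cna(op_concat(x, dif), p, slope = slope), x)
}

#' Additive attention gate
#'
#' `a = sigmoid(psi(relu(Wg gate + Wx skip)))` with intermediate channels
#' half the skip channels and a single-channel output, broadcast over the
#' skip's channels: the returned tensor is `a * skip`.  The gate must already
#' live on the skip's grid (it is the transposed-convolution upsampled
#' decoder feature).
#'
#' @param skip encoder skip feature.
#' @param gate decoder feature, same spatial grid as `skip`.
#' @param p gate weights (`wg`, `wx`, `psi`).
#' @param return_coefficients also return the attention map.
#' @return gated skip tensor, or a list `(gated, attention)` when
#'   `return_coefficients = TRUE`.
#' @export
attention_gate <- function(skip, gate, p, return_coefficients = FALSE) {
  q <- op_relu(op_add(op_conv3d(gate, p$wg$w, p$wg$b),
                      op_conv3d(skip, p$wx$w, p$wx$b)))
  a <- op_sigmoid(op_conv3d(q, p$psi$w, p$psi$b))
  out <- op_gate(skip, a)
  if (return_coefficients) list(gated = out, attention = a) else out
}

#' Full network forward pass
#'
#' @param x input tensor stored (D,H,W,C,B) — a plain array for inference or
#'   a tape node during training.
#' @param cfg an [arch_config()].
#' @param weights nested weight list from [network_init()] (arrays or
#'   parameter nodes).
#' @return list of per-level logits, deepest decoder level first; entry i has
#'   `cfg$head_classes[i]` channels on the grid of encoder level
#'   `n_levels - i`.
#' @export
network_forward <- function(x, cfg, weights) {
  dm <- dim(ag_value(x))
  check_patch(cfg, dm[1:3])
  if (dm[4] != cfg$in_channels) stop("input channel mismatch")
  s <- stride_schedule(cfg)
  L <- cfg$n_levels
  skips <- vector("list", L)
  h <- .cna(x, weights$stem)
  for (l in seq_len(L)) {
    p <- weights$encoder[[l]]
    if (l > 1L) h <- .cna(h, p$down, stride = s[l - 1L, ])
    h <- msc_block_forward(h, p$msc)
    if (!is.null(p$se)) h <- se_block_forward(h, p$se, cfg$flip_axis)
    skips[[l]] <- h
  }
  logits <- vector("list", L - 1L)
  dec <- skips[[L]]
  for (i in seq_len(L - 1L)) {
    l <- L - i
    p <- weights$decoder[[i]]
    up <- op_convt3d(dec, p$up$w, p$up$b)
    gated <- attention_gate(skips[[l]], up, p$gate)
    dec <- .cna(op_concat(up, gated), p$fuse)
    logits[[i]] <- op_conv3d(dec, p$head$w, p$head$b)
  }
  logits
}

#' Wrap checkpoint arrays as trainable parameter nodes
#' @keywords internal
params_to_nodes <- function(w) {
  if (is.list(w)) lapply(w, params_to_nodes) else ag_param(w)
}

#' Extract plain arrays from a (possibly node-bearing) weight tree
#' @keywords internal
params_to_arrays <- function(w) {
  if (is_node(w)) return(w$value)
  if (is.list(w)) lapply(w, params_to_arrays) else w
}

#' Flatten a weight tree into a list of leaf nodes
#' @keywords internal
flatten_params <- function(w) {
  if (is_node(w)) return(list(w))
  if (is.list(w)) return(do.call(c, lapply(w, flatten_params)))
  list()
}
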