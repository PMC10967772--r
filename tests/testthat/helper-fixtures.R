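# Shared fixtures: tiny architectures and reference (oracle) implementations
# used across test files.  All oracles are deliberately naive nested loops,
# independent of the package's GEMM/accumulation code paths.

tiny_arch <- function(...) {
  args <- utils::modifyList(
    list(n_levels = 3L, channels = c(4L, 6L, 8L), msc_kernels = c(5L),
         se_levels = c(2L, 3L), n_d_strides = 1L, ref_patch = c(4L, 8L, 8L)),
    list(...))
  do.call(arch_config, args)
}

tiny_phantom_params <- function(...) {
  # small grid, same anisotropy as the default
  args <- utils::modifyList(
    list(grid_shape = c(10L, 64L, 48L), spacing = c(5, 0.4, 0.4),
         head_axes = c(22, 11, 8.5), ic_center = c(0, 0, 4),
         ic_axes = c(4, 2.5, 2), ip_axes = c(7, 4, 3.2)),
    list(...))
  do.call(phantom_params, args)
}

# naive dense 3-D convolution, same weight layout as the package
# x (D,H,W,C,B), w (kd,kh,kw,Cin,Cout)
oracle_conv3d <- function(x, w, b = NULL, stride = c(1, 1, 1), pad = NULL) {
  d <- dim(x); wd <- dim(w)
  if (is.null(pad)) pad <- wd[1:3] %/% 2
  if (is.null(b)) b <- numeric(wd[5])
  os <- (d[1:3] + 2 * pad - wd[1:3]) %/% stride + 1
  y <- array(0, c(os, wd[5], d[5]))
  for (bb in seq_len(d[5])) for (co in seq_len(wd[5]))
    for (wo in seq_len(os[3])) for (ho in seq_len(os[2])) for (do_ in seq_len(os[1])) {
      acc <- b[co]
      for (ci in seq_len(wd[4])) for (zw in seq_len(wd[3]))
        for (zh in seq_len(wd[2])) for (zd in seq_len(wd[1])) {
          di <- (do_ - 1) * stride[1] + zd - pad[1]
          hi <- (ho - 1) * stride[2] + zh - pad[2]
          wi <- (wo - 1) * stride[3] + zw - pad[3]
          if (di >= 1 && di <= d[1] && hi >= 1 && hi <= d[2] &&
              wi >= 1 && wi <= d[3])
            acc <- acc + x[di, hi, wi, ci, bb] * w[zd, zh, zw, ci, co]
        }
      y[do_, ho, wo, co, bb] <- acc
    }
  y
}

oracle_dwconv3d <- function(x, w, b = NULL) {
  d <- dim(x); wd <- dim(w)
  wfull <- array(0, c(wd[1:3], d[4], d[4]))
  for (c in seq_len(d[4])) wfull[, , , c, c] <- w[, , , c]
  oracle_conv3d(x, wfull, b)
}

oracle_instnorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (bb in seq_len(d[5])) for (c in seq_len(d[4])) {
    s <- x[, , , c, bb]
    m <- mean(s)
    v <- mean((s - m)^2)
    y[, , , c, bb] <- gamma[c] * (s - m) / sqrt(v + eps) + beta[c]
  }
  y
}

oracle_lrelu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)

# Eq-style MSC block oracle built only from the naive primitives above
oracle_msc <- function(x, p) {
  xp <- oracle_lrelu(oracle_instnorm(oracle_conv3d(x, p$conv$w, p$conv$b),
                                     p$conv$gamma, p$conv$beta))
  u <- oracle_dwconv3d(xp, p$dw3$w, p$dw3$b)
  s <- u
  for (sc in p$scales) {
    v <- oracle_dwconv3d(u, sc$inplane$w, sc$inplane$b)
    v <- oracle_dwconv3d(v, sc$throughplane$w, sc$throughplane$b)
    s <- s + v
  }
  oracle_lrelu(oracle_instnorm(oracle_conv3d(s, p$fuse$w, p$fuse$b),
                               p$fuse$gamma, p$fuse$beta)) + xp
}

oracle_se <- function(x, p, flip_axis = 3L) {
  d <- dim(x)
  idx <- rev(seq_len(d[flip_axis]))
  fl <- switch(flip_axis, x[idx, , , , , drop = FALSE],
               x[, idx, , , , drop = FALSE], x[, , idx, , , drop = FALSE])
  dif <- x - fl
  cc <- array(0, c(d[1:3], 2 * d[4], d[5]))
  cc[, , , seq_len(d[4]), ] <- x
  cc[, , , d[4] + seq_len(d[4]), ] <- dif
  oracle_lrelu(oracle_instnorm(oracle_conv3d(cc, p$w, p$b),
                               p$gamma, p$beta)) + x
}

oracle_gate <- function(skip, gate, p) {
  q <- oracle_conv3d(gate, p$wg$w, p$wg$b) + oracle_conv3d(skip, p$wx$w, p$wx$b)
  q <- pmax(q, 0)
  a <- 1 / (1 + exp(-oracle_conv3d(q, p$psi$w, p$psi$b)))
  d <- dim(skip)
  out <- skip
  for (c in seq_len(d[4])) out[, , , c, ] <- skip[, , , c, ] * a[, , , 1, ]
  out
}

# pure-R surface distance oracle (boundary = 6-connectivity, edge counts
# as background), brute-force over all boundary pairs
oracle_surface <- function(pred, truth, spacing) {
  boundary <- function(m) {
    d <- dim(m)
    pad <- array(FALSE, d + 2)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
    idx <- which(m, arr.ind = TRUE)
    keep <- apply(idx, 1, function(v) {
      p <- v + 1
      !(pad[p[1] - 1, p[2], p[3]] && pad[p[1] + 1, p[2], p[3]] &&
          pad[p[1], p[2] - 1, p[3]] && pad[p[1], p[2] + 1, p[3]] &&
          pad[p[1], p[2], p[3] - 1] && pad[p[1], p[2], p[3] + 1])
    })
    idx[keep, , drop = FALSE]
  }
  bp <- boundary(pred); bt <- boundary(truth)
  dists <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      min(sqrt(colSums((t(b) - a[i, ])^2 * spacing^2)))
    }, numeric(1))
  }
  sp <- sweep(bp, 2, spacing, `*`); st <- sweep(bt, 2, spacing, `*`)
  d_pt <- vapply(seq_len(nrow(sp)), function(i)
    min(sqrt(rowSums(sweep(st, 2, sp[i, ])^2))), numeric(1))
  d_tp <- vapply(seq_len(nrow(st)), function(i)
    min(sqrt(rowSums(sweep(sp, 2, st[i, ])^2))), numeric(1))
  list(hd95 = stats::quantile(c(d_pt, d_tp), 0.95, names = FALSE),
       assd = (mean(d_pt) + mean(d_tp)) / 2)
}
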