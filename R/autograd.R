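# Reverse-mode autodiff tape.
#
# A node is an environment holding `value` (a numeric array), `grad`
# (accumulated during the backward pass), the parent nodes it was computed
# from, and a closure mapping the node's output gradient to per-parent
# gradients.  Operations below accept either plain arrays or nodes; when any
# input carries a tape the result does too, so the same block code serves
# training (taped) and inference (plain arrays, immediately collectable).

.ag_env <- new.env(parent = emptyenv())
.ag_env$counter <- 0L

#' @keywords internal
ag_node <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  .ag_env$counter <- .ag_env$counter + 1L
  e$id <- .ag_env$counter
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  class(e) <- "ag_node"
  e
}

#' Create a trainable parameter node
#' @keywords internal
ag_param <- function(value) ag_node(value)

is_node <- function(x) inherits(x, "ag_node")

#' Underlying array of a node (or the object itself)
#' @keywords internal
ag_value <- function(x) if (is_node(x)) x$value else x

.accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Run the backward pass from a scalar loss node
#'
#' Accumulates gradients into every reachable node's `grad` field.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  # iterative topological order (DFS, post-order)
  order <- vector("list", 64L)
  n_ord <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, i = 0L))
  assign(as.character(loss$id), TRUE, envir = visited)
  while (length(stack)) {
    top <- stack[[length(stack)]]
    node <- top$node
    kids <- Filter(is_node, node$parents)
    if (top$i < length(kids)) {
      stack[[length(stack)]]$i <- top$i + 1L
      child <- kids[[top$i + 1L]]
      key <- as.character(child$id)
      if (!exists(key, envir = visited, inherits = FALSE)) {
        assign(key, TRUE, envir = visited)
        stack[[length(stack) + 1L]] <- list(node = child, i = 0L)
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  loss$grad <- 1
  for (k in seq(n_ord, 1L)) {
    node <- order[[k]]
    if (is.null(node$backward) || is.null(node$grad)) next
    gs <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (is_node(p) && !is.null(gs[[j]])) .accum(p, gs[[j]])
    }
  }
  invisible(NULL)
}

#' Clear gradients on a (possibly nested) list of parameter nodes
#' @keywords internal
ag_zero_grad <- function(params) {
  rapply(params, function(p) { if (is_node(p)) p$grad <- NULL; NULL },
         classes = "ANY", how = "unlist")
  invisible(NULL)
}

.any_node <- function(...) any(vapply(list(...), is_node, logical(1)))

# ---- tensor ops -----------------------------------------------------------

#' 3-D convolution (dense), stride/pad per axis, weight (kd,kh,kw,Cin,Cout)
#' @keywords internal
op_conv3d <- function(x, w, b = NULL, stride = c(1L, 1L, 1L), pad = NULL) {
  wv <- ag_value(w)
  if (is.null(pad)) pad <- as.integer(dim(wv)[1:3] %/% 2L)
  xv <- ag_value(x)
  y <- .cpp_conv3d_fwd(xv, wv, ag_value(b), as.integer(stride), as.integer(pad))
  if (!.any_node(x, w, b)) return(y)
  ag_node(y, parents = list(x, w, b), backward = function(gy) {
    bw <- .cpp_conv3d_bwd(xv, wv, gy, as.integer(stride), as.integer(pad),
                          is_node(x), is_node(w))
    list(if (is_node(x)) bw$gx, if (is_node(w)) bw$gw,
         if (is_node(b)) bw$gb)
  })
}

#' Depthwise 3-D convolution, stride 1, same padding
#' @keywords internal
op_dwconv3d <- function(x, w, b = NULL) {
  wv <- ag_value(w)
  pad <- as.integer(dim(wv)[1:3] %/% 2L)
  xv <- ag_value(x)
  y <- .cpp_dwconv3d_fwd(xv, wv, ag_value(b), pad)
  if (!.any_node(x, w, b)) return(y)
  ag_node(y, parents = list(x, w, b), backward = function(gy) {
    bw <- .cpp_dwconv3d_bwd(xv, wv, gy, pad, is_node(x), is_node(w))
    list(if (is_node(x)) bw$gx, if (is_node(w)) bw$gw,
         if (is_node(b)) bw$gb)
  })
}

#' Transposed 3-D convolution with kernel = stride, weight (Cin,Cout,sd,sh,sw)
#' @keywords internal
op_convt3d <- function(x, w, b = NULL) {
  wv <- ag_value(w)
  xv <- ag_value(x)
  y <- .cpp_convt3d_fwd(xv, wv, ag_value(b))
  if (!.any_node(x, w, b)) return(y)
  ag_node(y, parents = list(x, w, b), backward = function(gy) {
    bw <- .cpp_convt3d_bwd(xv, wv, gy, is_node(x), is_node(w))
    list(if (is_node(x)) bw$gx, if (is_node(w)) bw$gw,
         if (is_node(b)) bw$gb)
  })
}

#' Instance normalisation with learned affine (gamma, beta per channel)
#' @keywords internal
op_instancenorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ag_value(x)
  fw <- .cpp_instnorm_fwd(xv, ag_value(gamma), ag_value(beta), eps)
  if (!.any_node(x, gamma, beta)) return(fw$y)
  ag_node(fw$y, parents = list(x, gamma, beta), backward = function(gy) {
    bw <- .cpp_instnorm_bwd(xv, gy, ag_value(gamma), fw$mu, fw$istd,
                            is_node(x))
    list(if (is_node(x)) bw$gx,
         if (is_node(gamma)) bw$ggamma,
         if (is_node(beta)) bw$gbeta)
  })
}

#' @keywords internal
op_leaky_relu <- function(x, slope = 0.01) {
  xv <- ag_value(x)
  y <- .cpp_leaky_relu_fwd(xv, slope)
  if (!is_node(x)) return(y)
  ag_node(y, parents = list(x), backward = function(gy) {
    list(.cpp_leaky_relu_bwd(xv, gy, slope))
  })
}

#' @keywords internal
op_relu <- function(x) {
  xv <- ag_value(x)
  y <- pmax(xv, 0)
  dim(y) <- dim(xv)
  if (!is_node(x)) return(y)
  ag_node(y, parents = list(x), backward = function(gy) {
    gx <- gy * (xv > 0)
    dim(gx) <- dim(xv)
    list(gx)
  })
}

#' @keywords internal
op_sigmoid <- function(x) {
  xv <- ag_value(x)
  y <- 1 / (1 + exp(-xv))
  dim(y) <- dim(xv)
  if (!is_node(x)) return(y)
  ag_node(y, parents = list(x), backward = function(gy) {
    gx <- gy * y * (1 - y)
    dim(gx) <- dim(xv)
    list(gx)
  })
}

#' Elementwise sum of two same-shape tensors
#' @keywords internal
op_add <- function(x, y) {
  xv <- ag_value(x); yv <- ag_value(y)
  z <- xv + yv
  if (!.any_node(x, y)) return(z)
  ag_node(z, parents = list(x, y), backward = function(gz) {
    list(if (is_node(x)) gz, if (is_node(y)) gz)
  })
}

#' Elementwise difference
#' @keywords internal
op_sub <- function(x, y) {
  xv <- ag_value(x); yv <- ag_value(y)
  z <- xv - yv
  if (!.any_node(x, y)) return(z)
  ag_node(z, parents = list(x, y), backward = function(gz) {
    list(if (is_node(x)) gz, if (is_node(y)) -gz)
  })
}

#' Gate a C-channel tensor with a single-channel attention map (broadcast)
#' @keywords internal
op_gate <- function(x, a) {
  xv <- ag_value(x); av <- ag_value(a)
  dm <- dim(xv)
  C <- dm[4]
  stopifnot(dim(av)[4] == 1L)
  arep <- av[, , , rep(1L, C), , drop = FALSE]
  z <- xv * arep
  dim(z) <- dm
  if (!.any_node(x, a)) return(z)
  ag_node(z, parents = list(x, a), backward = function(gz) {
    gx <- if (is_node(x)) { g <- gz * arep; dim(g) <- dm; g }
    ga <- if (is_node(a)) {
      prodg <- gz * xv
      dim(prodg) <- c(prod(dm[1:3]), C, dm[5])
      g <- array(0, c(dm[1:3], 1L, dm[5]))
      gm <- matrix(g, ncol = dm[5])
      for (b in seq_len(dm[5])) gm[, b] <- rowSums(prodg[, , b, drop = FALSE], dims = 1)
      dim(gm) <- c(dm[1:3], 1L, dm[5])
      gm
    }
    list(gx, ga)
  })
}

#' Concatenate along the channel axis
#' @keywords internal
op_concat <- function(x, y) {
  xv <- ag_value(x); yv <- ag_value(y)
  dx <- dim(xv); dy <- dim(yv)
  stopifnot(all(dx[c(1:3, 5)] == dy[c(1:3, 5)]))
  C1 <- dx[4]; C2 <- dy[4]
  z <- array(0, c(dx[1:3], C1 + C2, dx[5]))
  z[, , , seq_len(C1), ] <- xv
  z[, , , C1 + seq_len(C2), ] <- yv
  if (!.any_node(x, y)) return(z)
  ag_node(z, parents = list(x, y), backward = function(gz) {
    list(if (is_node(x)) gz[, , , seq_len(C1), , drop = FALSE],
         if (is_node(y)) gz[, , , C1 + seq_len(C2), , drop = FALSE])
  })
}

#' Mirror a tensor along one spatial axis (1 = D, 2 = H, 3 = W)
#' @keywords internal
op_flip <- function(x, axis = 3L) {
  xv <- ag_value(x)
  dm <- dim(xv)
  idx <- rev(seq_len(dm[axis]))
  fl <- function(a) switch(axis,
    a[idx, , , , , drop = FALSE],
    a[, idx, , , , drop = FALSE],
    a[, , idx, , , drop = FALSE])
  y <- fl(xv)
  if (!is_node(x)) return(y)
  ag_node(y, parents = list(x), backward = function(gy) list(fl(gy)))
}
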