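# The user-facing model object: one fitting function returning a classed
# S3 object with the usual verbs.

#' Desk-scale architecture (single CPU)
#'
#' A 5-level reduction of the default 7-level architecture: channels
#' (8, 16, 32, 64, 64), the same MSC kernel set, SE blocks at the deepest
#' four levels, D strided at the last two transitions, reference patch
#' 16 x 64 x 64.
#'
#' @param ... overrides passed to [arch_config()].
#' @export
desk_arch_config <- function(...) {
  defaults <- list(n_levels = 5L, channels = c(8L, 16L, 32L, 64L, 64L),
                   ref_patch = c(16L, 64L, 64L))
  do.call(arch_config, utils::modifyList(defaults, list(...)))
}

#' Fit the penumbra/core segmentation network
#'
#' Trains the 3-D encoder-decoder on preprocessed cases (see
#' [preprocess_case()]) and returns a fitted model that carries everything
#' needed for native-geometry prediction: weights, architecture, training
#' configuration, supervision scheme, fingerprint and the loss log.
#'
#' @param cases list of preprocessed cases (`image`, `label`, `spacing`).
#' @param fingerprint the [compute_fingerprint()] used to preprocess them.
#' @param arch an [arch_config()] (default [desk_arch_config()]).
#' @param train a [train_config()] (default [desk_train_config()]).
#' @param scheme optional [supervision_scheme()].
#' @param init optional starting weights.
#' @param verbose print per-epoch loss.
#' @return an object of class `strokeseg_model`.
#' @export
strokeseg_fit <- function(cases, fingerprint, arch = desk_arch_config(),
                          train = desk_train_config(), scheme = NULL,
                          init = NULL, verbose = FALSE) {
  fit <- train_loop(cases, arch, train, scheme = scheme, init = init,
                    verbose = verbose)
  structure(list(weights = fit$weights, arch = fit$arch, train = fit$train,
                 scheme = fit$scheme, fingerprint = fingerprint,
                 loss_log = fit$loss_log, n_cases = length(cases)),
            class = "strokeseg_model")
}

#' @export
print.strokeseg_model <- function(x, ...) {
  cat("3-D penumbra/core segmentation network\n")
  cat(sprintf("  levels: %d  channels: %s\n", x$arch$n_levels,
              paste(x$arch$channels, collapse = "/")))
  cat(sprintf("  trained: %d epochs x %d iters on %d cases (patch %s)\n",
              x$train$epochs, x$train$iters_per_epoch, x$n_cases,
              paste(x$train$patch_size, collapse = "x")))
  ll <- x$loss_log
  if (!is.null(ll) && nrow(ll))
    cat(sprintf("  loss: %.4f (first epoch mean) -> %.4f (last epoch mean)\n",
                mean(ll$loss[ll$epoch == min(ll$epoch)]),
                mean(ll$loss[ll$epoch == max(ll$epoch)])))
  invisible(x)
}

#' @export
summary.strokeseg_model <- function(object, ...) {
  ll <- object$loss_log
  per_epoch <- stats::aggregate(loss ~ epoch, data = ll, FUN = mean)
  out <- list(arch = object$arch, train = object$train,
              fingerprint = object$fingerprint,
              n_parameters = sum(vapply(flatten_params(
                params_to_nodes(object$weights)),
                function(p) length(p$value), numeric(1))),
              loss_per_epoch = per_epoch)
  class(out) <- "summary.strokeseg_model"
  out
}

#' @export
print.summary.strokeseg_model <- function(x, ...) {
  cat(sprintf("parameters: %d\n", x$n_parameters))
  cat(sprintf("median spacing: %s mm\n",
              paste(signif(x$fingerprint$median_spacing, 4), collapse = " x ")))
  cat("per-epoch mean loss:\n")
  print(x$loss_per_epoch, row.names = FALSE)
  invisible(x)
}

#' Segment a raw volume with a fitted model
#'
#' @param object a `strokeseg_model`.
#' @param image raw (D,H,W) array (native geometry).
#' @param spacing (D,H,W) spacing in mm.
#' @param tta flip test-time augmentation (default TRUE).
#' @param ... unused.
#' @return integer (D,H,W) label map over `{0,1,2}`.
#' @export
predict.strokeseg_model <- function(object, image, spacing, tta = TRUE, ...) {
  predict_case(image, spacing, object, tta = tta)
}

#' @export
plot.strokeseg_model <- function(x, ...) {
  ll <- x$loss_log
  per_epoch <- stats::aggregate(loss ~ epoch, data = ll, FUN = mean)
  graphics::plot(per_epoch$epoch, per_epoch$loss, type = "b",
                 xlab = "epoch", ylab = "mean training loss", ...)
  invisible(per_epoch)
}

#' @export
coef.strokeseg_model <- function(object, ...) object$weights
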