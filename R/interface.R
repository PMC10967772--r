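# NIfTI I/O and the command-line interface.
#
# Internal axis order is (D,H,W) with D the axial (thick-slice) axis.  NIfTI
# stores (x,y,z) with x fastest, which for axial head CT is (W,H,D); the
# boundary conversion is therefore a reversal of the axis order, so a file
# whose third (z) axis carries the 5 mm slices maps that axis to D.

#' Read a NIfTI volume
#'
#' @param path a readable 3-D NIfTI-1 file.
#' @param label validate the volume as an integer label map.
#' @return list `data` ((D,H,W) array, integer when `label`), `spacing`
#'   ((D,H,W) mm) and `pixdim` (the file's (x,y,z) spacing).
#' @export
read_nifti <- function(path, label = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(arr)), "-D: ", path)
  pd <- RNifti::pixdim(img)[1:3]
  data <- aperm(arr, c(3, 2, 1))
  if (label) {
    if (any(abs(data - round(data)) > 1e-6))
      stop("label volume contains non-integer values: ", path)
    data <- array(as.integer(round(data)), dim(data))
  }
  list(data = data, spacing = rev(pd), pixdim = pd)
}

#' Write a (D,H,W) volume as NIfTI
#'
#' @param data (D,H,W) array.
#' @param spacing (D,H,W) mm.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype storage type (e.g. `"float"`, `"uint8"` for labels).
#' @export
write_nifti <- function(data, spacing, path, datatype = "float") {
  arr <- aperm(data, c(3, 2, 1))
  attr(arr, "pixdim") <- rev(spacing)
  img <- RNifti::asNifti(arr, datatype = datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

.cli_usage <- function() {
  paste(
    "usage: strokeseg <command> [options]",
    "",
    "commands:",
    "  simulate    --n N --seed S --out-dir DIR",
    "              generate a phantom cohort (NIfTI pairs + manifest.csv)",
    "  preprocess  --cases DIR --out DIR --fingerprint FILE",
    "              fingerprint a cohort and write preprocessed volumes",
    "  train       --cases DIR --fingerprint FILE --out FILE [--seed S]",
    "              [--epochs E] [--iters I] fit the desk-scale network",
    "  predict     --checkpoint FILE --in FILE --out FILE",
    "              segment one NIfTI volume",
    "  evaluate    --pred-dir DIR --gt-dir DIR --out FILE",
    "              per-case and cohort metric CSVs",
    sep = "\n")
}

.cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("missing value for --", key)
    opts[[gsub("-", "_", key)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

.cli_need <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss))
    stop("missing required option(s): ", paste0("--", gsub("_", "-", miss),
                                                collapse = ", "))
}

.cli_simulate <- function(opts) {
  .cli_need(opts, c("n", "seed", "out_dir"))
  ch <- generate_cohort(as.integer(opts$n), seed = as.integer(opts$seed),
                        out_dir = opts$out_dir)
  message("wrote ", nrow(ch$manifest), " phantoms to ", opts$out_dir)
  0L
}

.cli_load_cases <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "case-[0-9]+\\.nii(\\.gz)?$",
                          full.names = TRUE))
  if (!length(imgs)) stop("no case-*.nii[.gz] volumes in ", dir)
  lapply(imgs, function(f) {
    lf <- sub("\\.nii(\\.gz)?$", "_label.nii\\1", f)
    v <- read_nifti(f)
    out <- list(image = v$data, spacing = v$spacing,
                id = sub("\\.nii(\\.gz)?$", "", basename(f)))
    if (file.exists(lf)) out$label <- read_nifti(lf, label = TRUE)$data
    out
  })
}

.cli_preprocess <- function(opts) {
  .cli_need(opts, c("cases", "out", "fingerprint"))
  cases <- .cli_load_cases(opts$cases)
  fp <- compute_fingerprint(cases)
  write_fingerprint(fp, opts$fingerprint)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  for (cs in cases) {
    pre <- preprocess_case(cs, fp)
    write_nifti(pre$image, pre$spacing,
                file.path(opts$out, paste0(cs$id, ".nii.gz")))
    if (!is.null(pre$label))
      write_nifti(pre$label, pre$spacing,
                  file.path(opts$out, paste0(cs$id, "_label.nii.gz")),
                  datatype = "uint8")
  }
  message("fingerprint: spacing ",
          paste(signif(fp$median_spacing, 4), collapse = " x "),
          " mm; preprocessed ", length(cases), " cases")
  0L
}

.cli_train <- function(opts) {
  .cli_need(opts, c("cases", "fingerprint", "out"))
  cases <- .cli_load_cases(opts$cases)
  fp <- read_fingerprint(opts$fingerprint)
  seed <- as.integer(opts$seed %||% 1L)
  tcfg <- desk_train_config(seed = seed)
  if (!is.null(opts$epochs)) tcfg$epochs <- as.integer(opts$epochs)
  if (!is.null(opts$iters)) tcfg$iters_per_epoch <- as.integer(opts$iters)
  pre <- lapply(cases, preprocess_case, fp = fp)
  model <- strokeseg_fit(pre, fingerprint = fp,
                         arch = desk_arch_config(), train = tcfg,
                         verbose = TRUE)
  saveRDS(model, opts$out)
  message("checkpoint written to ", opts$out)
  0L
}

.cli_predict <- function(opts) {
  .cli_need(opts, c("checkpoint", "in", "out"))
  model <- readRDS(opts$checkpoint)
  v <- read_nifti(opts$`in` %||% opts$in_)
  lab <- predict_case(v$data, v$spacing, model)
  write_nifti(lab, v$spacing, opts$out, datatype = "uint8")
  message("segmentation written to ", opts$out)
  0L
}

.cli_evaluate <- function(opts) {
  .cli_need(opts, c("pred_dir", "gt_dir", "out"))
  gts <- sort(list.files(opts$gt_dir, pattern = "_label\\.nii(\\.gz)?$",
                         full.names = TRUE))
  if (!length(gts)) stop("no *_label.nii[.gz] files in ", opts$gt_dir)
  truths <- list(); preds <- list(); spacings <- list()
  for (f in gts) {
    pf <- file.path(opts$pred_dir, basename(f))
    if (!file.exists(pf))
      pf <- file.path(opts$pred_dir, sub("_label", "", basename(f)))
    if (!file.exists(pf)) stop("missing prediction for ", basename(f))
    gt <- read_nifti(f, label = TRUE)
    pr <- read_nifti(pf, label = TRUE)
    truths[[length(truths) + 1L]] <- gt$data
    preds[[length(preds) + 1L]] <- pr$data
    spacings[[length(spacings) + 1L]] <- gt$spacing
  }
  ev <- evaluate_cohort(truths, preds, spacings, cutoff = NULL)
  utils::write.csv(ev$per_case, opts$out, row.names = FALSE)
  sumf <- sub("\\.csv$", "_summary.csv", opts$out)
  utils::write.csv(ev$summary, sumf, row.names = FALSE)
  message("per-case metrics: ", opts$out, "; cohort summary: ", sumf)
  0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: simulate, preprocess, train, predict, evaluate.  Each run
#' logs the package version and seed; returns a process exit status.
#'
#' @param args character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return integer exit status (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("--help", "-h", "help")) {
    cat(.cli_usage(), "\n")
    return(0L)
  }
  cmd <- args[1]
  handler <- switch(cmd,
                    simulate = .cli_simulate,
                    preprocess = .cli_preprocess,
                    train = .cli_train,
                    predict = .cli_predict,
                    evaluate = .cli_evaluate,
                    NULL)
  if (is.null(handler)) {
    message("unknown command: ", cmd, "\n", .cli_usage())
    return(2L)
  }
  opts <- tryCatch(.cli_opts(args[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts), "\n", .cli_usage())
    return(2L)
  }
  message("strokeseg ", as.character(utils::packageVersion("strokeseg")),
          " | command: ", cmd,
          if (!is.null(opts$seed)) paste0(" | seed: ", opts$seed) else "")
  status <- tryCatch(handler(opts), error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  as.integer(status)
}
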