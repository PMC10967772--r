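# Overlap and surface metrics, lesion volumetry, volume agreement and the
# dichotomised (70 mL-style cut-off) classification stack, computed per case
# in native geometry and aggregated over a cohort.

#' Dice similarity coefficient (percent)
#'
#' `2|A n B| / (|A| + |B|) * 100`; both masks empty scores 100 by
#' convention, exactly one empty scores 0.
#'
#' @param pred,truth logical/0-1 arrays of identical shape.
#' @return DSC in percent.
#' @export
dsc <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ")
  a <- sum(pred != 0); b <- sum(truth != 0)
  if (a + b == 0) return(100)
  2 * sum(pred != 0 & truth != 0) / (a + b) * 100
}

#' 95th-percentile Hausdorff and average symmetric surface distance
#'
#' Boundary voxels are foreground voxels with at least one face-adjacent
#' (6-connected) background neighbour (the volume edge counts as
#' background).  Distances are Euclidean under the physical spacing.  HD95
#' is the 95th percentile of the pooled directed boundary distances; ASSD is
#' the mean of the two mean directed distances.  If either mask is empty the
#' metrics are undefined and flagged.
#'
#' @param pred,truth masks of identical shape.
#' @param spacing (D,H,W) voxel spacing in mm.
#' @return list `hd95`, `assd` (mm; `NA` when undefined) and `defined`.
#' @export
surface_distances <- function(pred, truth, spacing) {
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ")
  pm <- array(pred != 0, dim(pred))
  tm <- array(truth != 0, dim(truth))
  if (!any(pm) || !any(tm))
    return(list(hd95 = NA_real_, assd = NA_real_, defined = FALSE))
  bp <- .cpp_boundary_voxels(pm)
  bt <- .cpp_boundary_voxels(tm)
  d_pt <- .cpp_directed_dists(bp, bt, spacing)
  d_tp <- .cpp_directed_dists(bt, bp, spacing)
  list(hd95 = stats::quantile(c(d_pt, d_tp), 0.95, names = FALSE),
       assd = (mean(d_pt) + mean(d_tp)) / 2,
       defined = TRUE)
}

#' Lesion volume in millilitres
#'
#' @param mask binary mask.
#' @param spacing (D,H,W) mm.
#' @return voxel count x voxel volume (mm^3) / 1000.
#' @export
lesion_volume_ml <- function(mask, spacing) {
  sum(mask != 0) * prod(spacing) / 1000
}

#' Volume agreement: Pearson correlation and Bland-Altman statistics
#'
#' @param pred_volumes,true_volumes paired volumes (mL), n >= 3.
#' @return list `r`, `ci` (Fisher-z 95 percent CI), `p`, `bias`
#'   (mean predicted - true), `loa` (bias +/- 1.96 sd of differences).
#' @export
volume_agreement <- function(pred_volumes, true_volumes) {
  if (length(pred_volumes) != length(true_volumes) || length(pred_volumes) < 3)
    stop("need >= 3 paired volumes")
  if (stats::sd(pred_volumes) < 1e-12 || stats::sd(true_volumes) < 1e-12)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(pred_volumes, true_volumes, method = "pearson")
  d <- pred_volumes - true_volumes
  bias <- mean(d)
  s <- stats::sd(d)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int), p = ct$p.value,
       bias = bias, loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s))
}

# Cohen's kappa with large-sample standard error; constant predictions give
# kappa 0 (chance agreement)
.kappa_stats <- function(truth, pred) {
  n <- length(truth)
  po <- mean(truth == pred)
  pe <- mean(truth) * mean(pred) + mean(!truth) * mean(!pred)
  if (abs(1 - pe) < 1e-12) return(list(kappa = 0, ci = c(NA, NA)))
  k <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  list(kappa = k, ci = c(max(-1, k - 1.96 * se), min(1, k + 1.96 * se)))
}

#' Dichotomised volume classification at a clinical cut-off
#'
#' Classes are defined by the true volume exceeding the cut-off; predicted
#' classes by thresholding the predicted volumes, with the continuous
#' predicted volume as the AUC score.  CIs: exact binomial (accuracy),
#' large-sample (kappa), seeded bootstrap or DeLong (AUC).
#'
#' @param pred_volumes,true_volumes paired volumes (mL).
#' @param cutoff volume threshold (mL), default 70 — the clinical infarct
#'   cut-off; scale it to the cohort's volume distribution for phantoms.
#' @param auc_ci `"bootstrap"` (2000 resamples, seeded) or `"delong"`.
#' @param boot_n,boot_seed bootstrap controls.
#' @return list `accuracy` (percent) with `accuracy_ci`, `kappa` with
#'   `kappa_ci`, `auc` with `auc_ci`, `confusion`, and `defined` flags for
#'   kappa/AUC when the ground truth is single-class.
#' @export
dichotomize_volumes <- function(pred_volumes, true_volumes, cutoff = 70,
                                auc_ci = c("bootstrap", "delong"),
                                boot_n = 2000, boot_seed = 1L) {
  auc_ci <- match.arg(auc_ci)
  if (length(pred_volumes) != length(true_volumes) || length(true_volumes) < 2)
    stop("need >= 2 paired volumes")
  truth <- true_volumes > cutoff
  pred <- pred_volumes > cutoff
  n <- length(truth)
  acc <- mean(truth == pred)
  bt <- stats::binom.test(sum(truth == pred), n)
  out <- list(accuracy = 100 * acc,
              accuracy_ci = 100 * as.numeric(bt$conf.int),
              confusion = table(factor(pred, c(FALSE, TRUE)),
                                factor(truth, c(FALSE, TRUE)),
                                dnn = c("pred", "truth")),
              cutoff = cutoff)
  if (length(unique(truth)) < 2L) {
    out$kappa <- NA_real_; out$kappa_ci <- c(NA, NA)
    out$auc <- NA_real_; out$auc_ci <- c(NA, NA)
    out$defined <- FALSE
    return(out)
  }
  ks <- .kappa_stats(truth, pred)
  out$kappa <- ks$kappa; out$kappa_ci <- ks$ci
  roc <- pROC::roc(response = truth, predictor = pred_volumes,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  out$auc <- as.numeric(pROC::auc(roc))
  out$auc_ci <- tryCatch({
    if (auc_ci == "bootstrap") {
      set.seed(boot_seed)
      ci <- suppressWarnings(pROC::ci.auc(roc, method = "bootstrap",
                                          boot.n = boot_n,
                                          progress = "none"))
    } else {
      ci <- suppressWarnings(pROC::ci.auc(roc, method = "delong"))
    }
    as.numeric(ci)[c(1, 3)]
  }, error = function(e) c(NA_real_, NA_real_))
  out$defined <- TRUE
  out
}

#' Per-case segmentation metrics for IP, IC and the merged lesion
#'
#' @param pred,truth integer label maps over `{0,1,2}` in native geometry.
#' @param spacing (D,H,W) mm.
#' @return data frame with one row per target (ip, ic, total): DSC (%),
#'   HD95/ASSD (mm, `NA` when undefined), predicted and true volumes (mL),
#'   and the `surface_defined` flag.
#' @export
case_metrics <- function(pred, truth, spacing) {
  targets <- list(ip = 1L, ic = 2L, total = c(1L, 2L))
  rows <- lapply(names(targets), function(nm) {
    pm <- pred %in% targets[[nm]]
    tm <- truth %in% targets[[nm]]
    dim(pm) <- dim(pred); dim(tm) <- dim(truth)
    sdist <- surface_distances(pm, tm, spacing)
    data.frame(target = nm,
               dsc = dsc(pm, tm),
               hd95 = sdist$hd95, assd = sdist$assd,
               surface_defined = sdist$defined,
               pred_volume_ml = lesion_volume_ml(pm, spacing),
               true_volume_ml = lesion_volume_ml(tm, spacing))
  })
  do.call(rbind, rows)
}

#' Evaluate a cohort of predictions
#'
#' Computes per-case metrics for IP (label 1), IC (label 2) and the merged
#' lesion, cohort mean +/- sd per metric (surface metrics over defined cases
#' only, with the exclusion count reported, or zero-filled with
#' `undefined_surfaces = "zero"`), total-lesion volume agreement and the
#' dichotomised classification, and optional covariate subgroup splits
#' (two-sample t-test on volume error / two-proportion test on
#' classification accuracy, two-sided alpha 0.05).
#'
#' @param truths,preds lists of paired native-space label maps.
#' @param spacings list of (D,H,W) spacings (or one shared spacing).
#' @param cutoff dichotomisation cut-off in mL (default 70); `NULL` uses the
#'   cohort median of the true total volumes.
#' @param metadata optional data frame of per-case covariates (factors).
#' @param undefined_surfaces `"exclude"` (default) or `"zero"`.
#' @return list `per_case` (data frame), `summary` (cohort mean/sd and
#'   exclusion counts), `volumes` ([volume_agreement()] on total volumes),
#'   `dichotomization`, `subgroups` (or NULL).
#' @export
evaluate_cohort <- function(truths, preds, spacings, cutoff = 70,
                            metadata = NULL,
                            undefined_surfaces = c("exclude", "zero")) {
  undefined_surfaces <- match.arg(undefined_surfaces)
  n <- length(truths)
  if (length(preds) != n) stop("unpaired cases")
  if (!is.list(spacings)) spacings <- rep(list(spacings), n)
  per <- lapply(seq_len(n), function(i) {
    cm <- case_metrics(preds[[i]], truths[[i]], spacings[[i]])
    cm$case <- i
    cm
  })
  per_case <- do.call(rbind, per)
  if (undefined_surfaces == "zero") {
    per_case$hd95[is.na(per_case$hd95)] <- 0
    per_case$assd[is.na(per_case$assd)] <- 0
  }
  summ <- do.call(rbind, lapply(split(per_case, per_case$target), function(d) {
    data.frame(target = d$target[1],
               dsc_mean = mean(d$dsc), dsc_sd = stats::sd(d$dsc),
               hd95_mean = mean(d$hd95, na.rm = TRUE),
               hd95_sd = stats::sd(d$hd95, na.rm = TRUE),
               assd_mean = mean(d$assd, na.rm = TRUE),
               assd_sd = stats::sd(d$assd, na.rm = TRUE),
               surface_excluded = sum(is.na(d$hd95)))
  }))
  tot <- per_case[per_case$target == "total", ]
  vol <- NULL
  if (n >= 3 && stats::sd(tot$pred_volume_ml) > 1e-12 &&
      stats::sd(tot$true_volume_ml) > 1e-12)
    vol <- volume_agreement(tot$pred_volume_ml, tot$true_volume_ml)
  if (is.null(cutoff)) cutoff <- stats::median(tot$true_volume_ml)
  dich <- if (n >= 2) dichotomize_volumes(tot$pred_volume_ml,
                                          tot$true_volume_ml, cutoff)
  subgroups <- NULL
  if (!is.null(metadata)) {
    subgroups <- lapply(names(metadata), function(v) {
      f <- factor(metadata[[v]])
      if (nlevels(f) != 2L) return(NULL)
      err <- abs(tot$pred_volume_ml - tot$true_volume_ml)
      tt <- tryCatch(stats::t.test(err ~ f), error = function(e) NULL)
      correct <- (tot$pred_volume_ml > cutoff) == (tot$true_volume_ml > cutoff)
      pt <- tryCatch(suppressWarnings(
        stats::prop.test(tapply(correct, f, sum), tapply(correct, f, length))),
        error = function(e) NULL)
      list(variable = v, levels = levels(f),
           volume_error_p = if (!is.null(tt)) tt$p.value else NA_real_,
           accuracy_p = if (!is.null(pt)) pt$p.value else NA_real_,
           accuracy_by_level = tapply(correct, f, mean) * 100)
    })
    subgroups <- Filter(Negate(is.null), subgroups)
  }
  list(per_case = per_case, summary = summ, volumes = vol,
       dichotomization = dich, subgroups = subgroups)
}

#' Bland-Altman plot of total-lesion volumes
#'
#' @param pred_volumes,true_volumes paired volumes (mL).
#' @param ... passed to [graphics::plot()].
#' @export
bland_altman_plot <- function(pred_volumes, true_volumes, ...) {
  m <- (pred_volumes + true_volumes) / 2
  d <- pred_volumes - true_volumes
  bias <- mean(d); s <- stats::sd(d)
  graphics::plot(m, d, xlab = "Mean volume (mL)",
                 ylab = "Predicted - true (mL)", ...)
  graphics::abline(h = bias, lty = 1)
  graphics::abline(h = bias + c(-1.96, 1.96) * s, lty = 2)
  invisible(list(bias = bias, loa = bias + c(-1.96, 1.96) * s))
}
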