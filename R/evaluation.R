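#' Per-axis mean absolute error
#'
#' @param preds,targets n x 3 matrices of predicted and true shifts (mm).
#' @return Data frame with one row per axis (x, y, z): `mae` and `sd` of the
#'   absolute errors, in mm. With a single sample the std is 0 by convention.
#' @export
mae_per_axis <- function(preds, targets) {
  ae <- abs_errors(preds, targets)
  data.frame(axis = c("x", "y", "z"),
             mae = colMeans(ae),
             sd = apply(ae, 2, function(v) if (length(v) > 1) stats::sd(v) else 0))
}

abs_errors <- function(preds, targets) {
  preds <- as_nx3(preds); targets <- as_nx3(targets)
  if (nrow(preds) != nrow(targets) || nrow(preds) == 0)
    stop("predictions and targets must have equal, non-zero length")
  abs(preds - targets)
}

as_nx3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, 1, 3)
  if (ncol(x) != 3) x <- t(x)
  x
}

#' Relative mean absolute error (rMAE)
#'
#' Absolute errors are normalized per axis by the standard deviation
#' (sample, n-1) of that axis's targets, then pooled across the three axes
#' and summarized as mean and std. Dividing by the target spread makes the
#' metric comparable across motion magnitudes and axes.
#'
#' @inheritParams mae_per_axis
#' @return List with `mean`, `sd`, and `per_sample` (the per-sequence rMAE:
#'   mean over axes of the normalized absolute error, used for paired
#'   significance testing).
#' @export
rmae <- function(preds, targets) {
  targets <- as_nx3(targets)
  ae <- abs_errors(preds, targets)
  s <- apply(targets, 2, stats::sd)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("rMAE undefined: target variance is zero on at least one axis")
  rel <- sweep(ae, 2, s, `/`)
  list(mean = mean(rel), sd = stats::sd(as.vector(rel)),
       per_sample = rowMeans(rel))
}

#' Average correlation coefficient (aCC)
#'
#' Pearson correlation between predicted and true shifts, computed per axis,
#' averaged over the three axes and expressed in percent.
#'
#' @inheritParams mae_per_axis
#' @return Scalar percentage in [-100, 100].
#' @export
acc_metric <- function(preds, targets) {
  preds <- as_nx3(preds); targets <- as_nx3(targets)
  if (nrow(preds) != nrow(targets) || nrow(preds) < 2)
    stop("aCC needs at least two paired samples")
  r <- vapply(1:3, function(k) {
    if (stats::sd(preds[, k]) == 0 || stats::sd(targets[, k]) == 0)
      stop("aCC undefined: degenerate variance on axis ", k)
    stats::cor(preds[, k], targets[, k])
  }, numeric(1))
  100 * mean(r)
}

#' Paired Wilcoxon signed-rank comparison of per-sample errors
#'
#' Two-sided paired signed-rank test on per-sample error values (typically
#' the per-sequence rMAE of two models on the same test set). Zero
#' differences are dropped, the standard signed-rank convention.
#'
#' @param errors_a,errors_b equal-length numeric vectors (n >= 6) of paired
#'   per-sample errors.
#' @param alpha significance level.
#' @return List with `statistic`, `p`, `significant`, `n_effective`.
#' @export
wilcoxon_compare <- function(errors_a, errors_b, alpha = 0.05) {
  if (length(errors_a) != length(errors_b))
    stop("paired samples must have equal length")
  if (length(errors_a) < 6)
    stop("at least 6 paired samples are required")
  d <- errors_a - errors_b
  keep <- d != 0
  if (!any(keep))
    return(list(statistic = NA_real_, p = 1, significant = FALSE,
                n_effective = 0L))
  wt <- stats::wilcox.test(errors_a[keep], errors_b[keep], paired = TRUE,
                           exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       significant = wt$p.value < alpha, n_effective = sum(keep))
}

#' Mean error binned by motion magnitude
#'
#' Samples are assigned to `n_bins` quantile bins of the true shift magnitude
#' ||shift||; within each bin the mean Euclidean error ||pred - target|| is
#' reported. Increasing per-bin error with magnitude indicates degradation
#' for larger motion.
#'
#' @inheritParams mae_per_axis
#' @param n_bins number of quantile bins.
#' @return Data frame: `bin`, `lo`, `hi` (magnitude edges, mm), `n`, `mae`
#'   (mean Euclidean error, mm).
#' @export
magnitude_binned_mae <- function(preds, targets, n_bins = 4L) {
  preds <- as_nx3(preds); targets <- as_nx3(targets)
  n <- nrow(preds)
  if (n < n_bins) stop("fewer samples than bins")
  mag <- sqrt(rowSums(targets^2))
  err <- sqrt(rowSums((preds - targets)^2))
  edges <- stats::quantile(mag, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(mag, breaks = unique(c(-Inf, edges[-c(1, n_bins + 1)], Inf)),
             labels = FALSE)
  out <- data.frame(
    bin = seq_len(n_bins),
    lo = edges[seq_len(n_bins)],
    hi = edges[-1],
    n = as.integer(tabulate(bin, n_bins)),
    mae = vapply(seq_len(n_bins), function(b) mean(err[bin == b]), numeric(1)))
  rownames(out) <- NULL
  out
}

#' Evaluate a trained model on held-out sequences
#'
#' Runs the model over the selected sequences and assembles the standard
#' report: per-axis MAE, pooled rMAE, aCC, magnitude-binned errors.
#'
#' @param model a trained `oct_model`.
#' @param dataset an `oct_dataset`.
#' @param roi_ids ROIs to evaluate on (default: all).
#' @param augment optional evaluation-time augmentation, a function applied
#'   to each sequence before prediction (labels adjusted by the augmentation
#'   itself, e.g. motion-mode rotation).
#' @return An `eval_report`: `mae` (per-axis data frame), `rmae_mean`,
#'   `rmae_sd`, `acc_percent`, `per_bin` (data frame), `n`, plus `preds`,
#'   `targets` and `per_sample_rmae` for downstream comparison.
#' @export
evaluate_model <- function(model, dataset, roi_ids = NULL, augment = NULL) {
  roi <- vapply(dataset$sequences, function(s) s$roi_id, integer(1))
  idx <- if (is.null(roi_ids)) seq_along(dataset$sequences) else which(roi %in% roi_ids)
  if (length(idx) == 0) stop("no sequences in the requested ROIs")
  if (!is.null(augment)) {
    # augmentation may alter labels (motion-mode rotation), so collect both
    seqs <- lapply(dataset$sequences[idx], augment)
    ds <- structure(list(sequences = seqs), class = "oct_dataset")
    targets <- t(vapply(seqs, function(s) s$shifts[5, ], numeric(3)))
    preds <- predict_batch(model, ds)
  } else {
    targets <- dataset_targets(dataset, idx)$tn
    preds <- predict_batch(model, dataset, idx)
  }
  rm_ <- rmae(preds, targets)
  structure(list(mae = mae_per_axis(preds, targets),
                 rmae_mean = rm_$mean, rmae_sd = rm_$sd,
                 acc_percent = acc_metric(preds, targets),
                 per_bin = magnitude_binned_mae(preds, targets),
                 n = nrow(preds), preds = preds, targets = targets,
                 per_sample_rmae = rm_$per_sample),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d\n", x$n))
  cat(sprintf("  MAE  x %.4f+-%.4f  y %.4f+-%.4f  z %.4f+-%.4f mm\n",
              x$mae$mae[1], x$mae$sd[1], x$mae$mae[2], x$mae$sd[2],
              x$mae$mae[3], x$mae$sd[3]))
  cat(sprintf("  rMAE %.4f+-%.4f   aCC %.2f%%\n", x$rmae_mean, x$rmae_sd,
              x$acc_percent))
  invisible(x)
}

#' Robustness sweep over evaluation-time perturbations
#'
#' Re-evaluates a trained model while perturbing the held-out sequences:
#' either progressive axial-axis rotations (in noise and motion label modes)
#' or B-scan motion distortions at several probabilities and shift sizes.
#' Augmentation is applied at evaluation time only.
#'
#' @param model a trained `oct_model`.
#' @param dataset an `oct_dataset`.
#' @param axis `"rotation"` or `"distortion"`.
#' @param levels rotation: numeric alpha_max values in degrees (crossed with
#'   both modes); distortion: numeric p_dist values (crossed with shift_px
#'   1 and 2).
#' @param roi_ids ROIs to evaluate on.
#' @param seed seed for the stochastic distortion augmentation.
#' @return Data frame with one row per sweep cell: the level columns plus
#'   `rmae_mean`, `rmae_sd`, `acc_percent`, `mae_x`, `mae_y`, `mae_z`, `n`.
#' @export
robustness_sweep <- function(model, dataset,
                             axis = c("rotation", "distortion"),
                             levels = NULL, roi_ids = NULL, seed = 1L) {
  axis <- match.arg(axis)
  if (is.null(levels))
    levels <- if (axis == "rotation") c(2, 5, 10, 20) else c(0.1, 0.25, 0.5)
  grid <- if (axis == "rotation") {
    expand.grid(alpha_max = levels, mode = c("noise", "motion"),
                stringsAsFactors = FALSE)
  } else {
    expand.grid(p_dist = levels, shift_px = c(1L, 2L))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    set.seed(seed + i)
    aug <- if (axis == "rotation") {
      function(s) rotate_sequence(s, grid$alpha_max[i], grid$mode[i])
    } else {
      function(s) distort_sequence(s, grid$p_dist[i], grid$shift_px[i])
    }
    rep_ <- evaluate_model(model, dataset, roi_ids, augment = aug)
    cbind(grid[i, , drop = FALSE],
          data.frame(rmae_mean = rep_$rmae_mean, rmae_sd = rep_$rmae_sd,
                     acc_percent = rep_$acc_percent,
                     mae_x = rep_$mae$mae[1], mae_y = rep_$mae$mae[2],
                     mae_z = rep_$mae$mae[3], n = rep_$n))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path output JSON path; per-sample errors are written alongside as
#'   CSV when `per_sample_csv` is given.
#' @param per_sample_csv optional CSV path for per-sample predictions,
#'   targets and rMAE values.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, per_sample_csv = NULL) {
  obj <- list(n = report$n,
              mae = report$mae,
              rmae_mean = report$rmae_mean, rmae_sd = report$rmae_sd,
              acc_percent = report$acc_percent,
              per_bin = report$per_bin)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(per_sample_csv)) {
    df <- data.frame(report$preds, report$targets, report$per_sample_rmae)
    names(df) <- c("pred_x", "pred_y", "pred_z",
                   "target_x", "target_y", "target_z", "rmae")
    utils::write.csv(df, per_sample_csv, row.names = FALSE)
  }
  invisible(path)
}
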