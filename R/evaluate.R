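trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' ROC curve and AUC for a gene ranking
#'
#' Genes are ranked by `score` ascending (smaller = more significant, e.g. a
#' direction-specific p-value). The true/false positive rates are swept over
#' all distinct thresholds and the AUC is computed by the trapezoid rule, so
#' tied scores contribute diagonal segments (half credit), matching the
#' rank-statistic definition of the AUC.
#'
#' @param score Numeric ranking values, one per gene.
#' @param label Logical; TRUE for genes that are true hits of the evaluated
#'   direction. Genes of the opposite direction count as negatives.
#' @return A `roc_curve` list: `points` (data frame `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_curve <- function(score, label) {
  if (length(score) != length(label)) stop("score and label must be parallel")
  label <- as.logical(label)
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one true and one false label")
  }
  o <- order(score)
  lab <- label[o]
  sc <- score[o]
  # keep one point per distinct threshold: the last index of each tied run
  last <- c(sc[-1] != sc[-length(sc)], TRUE)
  tpr <- c(0, cumsum(lab)[last] / n_pos)
  fpr <- c(0, cumsum(!lab)[last] / n_neg)
  structure(
    list(points = data.frame(fpr = fpr, tpr = tpr),
         auc = trapezoid(fpr, tpr)),
    class = "roc_curve"
  )
}

#' Vertically average ROC curves
#'
#' Each member curve is treated as a step function (TPR achieved at FPR <= f)
#' and evaluated on a common equispaced FPR grid; the TPRs are averaged
#' pointwise and the AUC of the averaged curve is returned.
#'
#' @param curves List of `roc_curve` objects.
#' @param grid_size Number of grid points on the unit FPR interval.
#' @return List with `fpr` (grid), `tpr` (averaged), `auc`, `n_curves`.
#' @export
average_roc <- function(curves, grid_size = 1001L) {
  if (length(curves) == 0L) stop("need at least one ROC curve")
  grid <- seq(0, 1, length.out = grid_size)
  tprs <- vapply(curves, function(cv) {
    pts <- cv$points
    # max TPR per distinct FPR, then left-continuous step interpolation
    agg <- tapply(pts$tpr, pts$fpr, max)
    fpr <- as.numeric(names(agg))
    approx(fpr, as.numeric(agg), xout = grid, method = "constant",
           f = 0, rule = 2)$y
  }, numeric(grid_size))
  mean_tpr <- rowMeans(tprs)
  list(fpr = grid, tpr = mean_tpr, auc = trapezoid(grid, mean_tpr),
       n_curves = length(curves))
}

#' Recall, precision and F1 of a called gene set
#'
#' Recall is the fraction of true hits recovered, precision the fraction of
#' calls that are true hits, and `F1 = 2 * recall * precision /
#' (recall + precision)` their harmonic mean. An empty call set yields
#' (0, 0, 0) by convention; `1 - precision` is the empirical FDR.
#'
#' @param called Character vector of called gene ids.
#' @param truth Character vector: the true hit genes of the direction.
#' @return Named numeric vector `recall`, `precision`, `f1`.
#' @export
recall_precision_f1 <- function(called, truth) {
  if (length(truth) == 0L) stop("truth set must be non-empty")
  tp <- length(intersect(called, truth))
  recall <- tp / length(truth)
  precision <- if (length(called) == 0L) 0 else tp / length(called)
  f1 <- if (recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else {
    0
  }
  c(recall = recall, precision = precision, f1 = f1)
}

#' Simulation benchmark of the screen test
#'
#' Simulates `n_datasets` independent screens (dataset seeds derived
#' deterministically from `master_seed` by one `sample.int` call), runs the
#' permutation test on each (Fisher-combining replicates when the simulation
#' config asks for several), and aggregates direction-specific metrics:
#' per-dataset ROC curves and their vertical average, AUC, and
#' recall/precision/F1 of the FDR-controlled call set, with standard errors.
#'
#' Evaluation convention: genes are ranked by the direction's p-value; the
#' positives are the true hits of `direction` and every other gene — including
#' true hits of the opposite direction — is a negative.
#'
#' @param sim_cfg A [sim_config].
#' @param test_cfg A [screen_test_config]; its `fdr_level` defines the call set.
#' @param n_datasets Number of simulated datasets.
#' @param direction "positive" or "negative" selection.
#' @param master_seed Integer master seed.
#' @return An `evaluation_report` list: `roc` (averaged curve), `auc`, metric
#'   means and standard errors, `per_dataset` data frame, `curves`, and
#'   metadata.
#' @export
run_benchmark <- function(sim_cfg, test_cfg = screen_test_config(), n_datasets = 50L,
                          direction = c("positive", "negative"),
                          master_seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(inherits(sim_cfg, "sim_config"))
  set.seed(master_seed)
  dataset_seeds <- sample.int(.Machine$integer.max - 1L, n_datasets)

  curves <- vector("list", n_datasets)
  per <- data.frame(dataset = seq_len(n_datasets), seed = dataset_seeds,
                    auc = NA_real_, recall = NA_real_, precision = NA_real_,
                    f1 = NA_real_, n_called = NA_integer_)
  for (k in seq_len(n_datasets)) {
    cfg_k <- sim_cfg
    cfg_k$seed <- dataset_seeds[k]
    sim <- simulate_screen(cfg_k)
    x <- if (length(sim$tables) == 1L) sim$tables[[1L]] else sim$tables
    res <- screen_test(x, test_cfg)

    truth_genes <- sim$truth$genes$gene[sim$truth$genes$direction == direction]
    label <- res$gene %in% truth_genes
    p <- if (direction == "positive") res$p_pos else res$p_neg
    fdr <- if (direction == "positive") res$fdr_pos else res$fdr_neg
    curves[[k]] <- roc_curve(p, label)
    called <- res$gene[fdr <= test_cfg$fdr_level]
    m <- recall_precision_f1(called, truth_genes)
    per$auc[k] <- curves[[k]]$auc
    per$recall[k] <- m["recall"]
    per$precision[k] <- m["precision"]
    per$f1[k] <- m["f1"]
    per$n_called[k] <- length(called)
  }

  avg <- average_roc(curves)
  se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  structure(
    list(
      roc = data.frame(fpr = avg$fpr, tpr = avg$tpr),
      auc = avg$auc,
      mean_auc = mean(per$auc),
      recall = mean(per$recall), recall_se = se(per$recall),
      precision = mean(per$precision), precision_se = se(per$precision),
      f1 = mean(per$f1), f1_se = se(per$f1),
      empirical_fdr = 1 - mean(per$precision),
      per_dataset = per,
      curves = curves,
      n_datasets = n_datasets,
      direction = direction,
      negatives_include_opposite_direction = TRUE,
      fdr_level = test_cfg$fdr_level,
      master_seed = master_seed
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (", x$direction, " selection, ",
      x$n_datasets, " datasets)\n", sep = "")
  cat(sprintf("  AUC of averaged ROC: %.4f (mean per-dataset AUC %.4f)\n",
              x$auc, x$mean_auc))
  cat(sprintf("  at FDR %.2f: recall %.3f +/- %.3f, precision %.3f +/- %.3f, F1 %.3f +/- %.3f\n",
              x$fdr_level, x$recall, x$recall_se %||% NA,
              x$precision, x$precision_se %||% NA, x$f1, x$f1_se %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
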