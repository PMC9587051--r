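# Evaluation toolkit: confusion matrices, one-vs-rest empirical ROC/auROC,
# sensitivity/specificity cutoff, bootstrap accuracy distributions, Fisher's
# exact comparison of two classifiers, and grouped k-fold out-of-sample
# testing with leave-one-category-out support.

#' Confusion matrix of stage classifications
#'
#' Rows are true stages, columns predicted stages. Also returns the
#' row-stochastic (row-normalized) variant, overall accuracy and per-stage
#' accuracy (the diagonal of the normalized matrix).
#'
#' @param truth,pred Equal-length character vectors of stage labels.
#' @param stages Label set fixing row/column order (default the canonical
#'   stages).
#' @return List with `counts`, `normalized`, `accuracy`,
#'   `per_stage_accuracy`.
#' @export
confusion_matrix <- function(truth, pred, stages = canonical_stages()) {
  if (length(truth) != length(pred)) stopf("truth and pred lengths differ")
  bad <- setdiff(unique(c(truth, pred)), stages)
  if (length(bad)) stopf("label(s) outside the stage set: %s",
                         paste(bad, collapse = ", "))
  tab <- table(factor(truth, levels = stages), factor(pred, levels = stages))
  counts <- unclass(as.matrix(tab))
  dimnames(counts) <- list(truth = stages, predicted = stages)
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, normalized = normalized,
       accuracy = sum(diag(counts)) / sum(counts),
       per_stage_accuracy = stats::setNames(diag(normalized), stages))
}

#' One-vs-rest ROC curve and auROC for one stage
#'
#' Empirical ROC on the stage's softmax score over all score thresholds,
#' with true positives defined by the benchmark labels. The curve starts at
#' (0,0), ends at (1,1); the area is the trapezoidal integral, which equals
#' the probability that a random positive outscores a random negative (ties
#' counting one half).
#'
#' @param scores Numeric vector of the stage's predicted probability per
#'   sample, or a samples x stages matrix with column names.
#' @param truth Character vector of true stage labels.
#' @param stage The positive stage.
#' @return List with `fpr`, `tpr`, `thresholds`, `auroc`.
#' @export
one_vs_rest_roc <- function(scores, truth, stage) {
  if (is.matrix(scores)) scores <- scores[, stage]
  pos <- truth == stage
  if (all(pos) || !any(pos)) {
    stopf("both classes must be present for stage '%s'", stage)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  if (fpr[length(fpr)] != 1 || tpr[length(tpr)] != 1) {
    fpr <- c(fpr, 1); tpr <- c(tpr, 1)
  }
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, thr), auroc = auroc)
}

#' Sensitivity and specificity curves with crossing cutoff
#'
#' Computes sensitivity(t) = P(score >= t | positive) and specificity(t) =
#' P(score <= t | negative) over a threshold grid (the sorted unique scores
#' plus the endpoints 0 and 1, so sensitivity(0) = specificity(1) = 1), and
#' locates the probability cutoff where the curves cross by linear
#' interpolation between adjacent grid points. Optional bootstrap standard
#' error bands.
#'
#' @param scores Numeric scores in `[0,1]`.
#' @param truth Logical (or two-valued) vector of positive-class membership.
#' @param n_boot Number of bootstrap resamples for SE bands (0 = none).
#' @param seed Seed for the bootstrap.
#' @return List with `thresholds`, `sensitivity`, `specificity`, `cutoff`,
#'   and (when requested) `sensitivity_se`, `specificity_se`.
#' @export
sens_spec_cutoff <- function(scores, truth, n_boot = 0, seed = NULL) {
  pos <- as.logical(truth)
  if (all(pos) || !any(pos)) stopf("both classes must be present")
  grid <- sort(unique(c(0, 1, scores)))
  curves <- function(s, p) {
    list(sens = vapply(grid, function(t) mean(s[p] >= t), numeric(1)),
         spec = vapply(grid, function(t) mean(s[!p] <= t), numeric(1)))
  }
  cv <- curves(scores, pos)
  d <- cv$sens - cv$spec
  cutoff <- NA_real_
  ix <- which(d == 0)
  if (length(ix)) {
    # exact ties can form a plateau (e.g. fully separated classes);
    # take its midpoint
    cutoff <- mean(range(grid[ix]))
  } else {
    sgn <- which(d[-1] * d[-length(d)] < 0)
    if (length(sgn)) {
      i <- sgn[1]
      # linear interpolation of the difference curve between grid points
      cutoff <- grid[i] + (grid[i + 1] - grid[i]) * d[i] / (d[i] - d[i + 1])
    }
  }
  out <- list(thresholds = grid, sensitivity = cv$sens, specificity = cv$spec,
              cutoff = cutoff)
  if (n_boot > 0) {
    bs <- with_seed(seed, {
      replicate(n_boot, {
        idx <- sample.int(length(scores), replace = TRUE)
        cb <- curves(scores[idx], pos[idx])
        rbind(cb$sens, cb$spec)
      })
    })
    out$sensitivity_se <- apply(bs[1, , ], 1, stats::sd)
    out$specificity_se <- apply(bs[2, , ], 1, stats::sd)
  }
  out
}

#' Bootstrap distribution of classification accuracy
#'
#' Resamples (truth, prediction) pairs with replacement `n_iter` times and
#' returns the accuracy distribution, its mean, the quartiles, and error-bar
#' positions defined as the 25th (75th) percentile minus (plus) the
#' interquartile range (plain quartile whiskers are also returned).
#'
#' @param truth,pred Equal-length label vectors.
#' @param n_iter Bootstrap iterations (default 5000).
#' @param seed Integer seed.
#' @return List with `accuracies`, `mean`, `q25`, `q75`, `iqr`, `bar_lower`,
#'   `bar_upper`.
#' @export
bootstrap_accuracy <- function(truth, pred, n_iter = 5000, seed = NULL) {
  if (length(truth) != length(pred) || length(truth) == 0) {
    stopf("truth and pred must be equal-length and non-empty")
  }
  correct <- truth == pred
  acc <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      mean(correct[sample.int(length(correct), replace = TRUE)])
    }, numeric(1))
  })
  q <- stats::quantile(acc, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  list(accuracies = acc, mean = mean(acc), q25 = q[1], q75 = q[2], iqr = iqr,
       bar_lower = q[1] - iqr, bar_upper = q[2] + iqr)
}

#' Fisher's exact comparison of two classifiers' accuracy
#'
#' Builds the 2 x 2 table `[[correct_a, n_a - correct_a], [correct_b,
#' n_b - correct_b]]`, computes the exact two-sided p-value from the
#' hypergeometric distribution, the sample odds ratio `(a*d)/(b*c)`, and a
#' Woolf 95% confidence interval (log-OR +/- 1.96 SE, with a 0.5 continuity
#' correction applied to every cell when any cell is zero).
#'
#' @param correct_a,n_a Correct count and total for classifier A.
#' @param correct_b,n_b Correct count and total for classifier B.
#' @return List with `odds_ratio`, `conf_int` (length 2), `p_value`,
#'   `table`.
#' @export
fisher_exact_comparison <- function(correct_a, n_a, correct_b, n_b) {
  if (n_a < 1 || n_b < 1) stopf("both groups must be non-empty")
  if (correct_a < 0 || correct_a > n_a || correct_b < 0 || correct_b > n_b) {
    stopf("correct counts must lie in [0, n]")
  }
  tab <- matrix(c(correct_a, n_a - correct_a, correct_b, n_b - correct_b),
                2, 2, byrow = TRUE)
  p <- fisher.test(tab)$p.value
  cells <- as.vector(t(tab))
  if (any(cells == 0)) cells <- cells + 0.5  # Haldane-Anscombe correction
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1.96, 1.96) * se)
  list(odds_ratio = or, conf_int = ci, p_value = p, table = tab)
}

#' Grouped k-fold out-of-sample evaluation
#'
#' Partitions the distinct values of a grouping key (subjects, stains,
#' species) into `k` folds — never individual records — so no group appears
#' in both the training and test side of any fold; trains and tests via a
#' user-supplied `trainer` callback on each fold; and reports per-fold
#' accuracies, their mean, and the element-wise mean of the fold confusion
#' matrices. With `mode = "leave_one_out"` every category forms its own test
#' fold and is removed from training entirely (out-of-sample stain/species
#' testing).
#'
#' @param m An `estrous_manifest` with `stage` set.
#' @param group_key Manifest column defining groups (`"subject_id"`,
#'   `"stain"`, `"species"`, ...).
#' @param k Number of folds (default 6); ignored for leave-one-out.
#' @param trainer `function(train_manifest, test_manifest) -> character`
#'   returning predicted stages for the test rows.
#' @param seed Integer seed for the fold shuffle.
#' @param mode `"kfold"` or `"leave_one_out"`.
#' @return List with `fold_accuracy`, `mean_accuracy`, `mean_confusion`,
#'   `folds` (test-group assignment).
#' @export
grouped_kfold_oos <- function(m, group_key = "subject_id", k = 6, trainer,
                              seed = NULL, mode = c("kfold", "leave_one_out")) {
  mode <- match.arg(mode)
  if (!group_key %in% names(m)) stopf("unknown group key '%s'", group_key)
  groups <- unique(m[[group_key]])
  folds <- if (mode == "leave_one_out") {
    as.list(groups)
  } else {
    if (length(groups) < k) {
      stopf("only %d distinct %s group(s) for k = %d; use a smaller k",
            length(groups), group_key, k)
    }
    shuffled <- with_seed(seed, sample(groups))
    split(shuffled, rep_len(seq_len(k), length(shuffled)))
  }
  stages <- canonical_stages()
  conf_sum <- matrix(0, length(stages), length(stages),
                     dimnames = list(truth = stages, predicted = stages))
  accs <- numeric(length(folds))
  for (i in seq_along(folds)) {
    test_groups <- folds[[i]]
    test_idx <- m[[group_key]] %in% test_groups
    train_m <- m[!test_idx, , drop = FALSE]
    test_m <- m[test_idx, , drop = FALSE]
    pred <- trainer(train_m, test_m)
    cm <- confusion_matrix(test_m$stage, pred, stages)
    conf_sum <- conf_sum + cm$counts
    accs[i] <- cm$accuracy
    ec_log("grouped_kfold_oos: fold %d (%s) accuracy %.3f", i,
           paste(test_groups, collapse = ","), accs[i])
  }
  list(fold_accuracy = accs, mean_accuracy = mean(accs),
       mean_confusion = conf_sum / length(folds), folds = folds)
}

#' Rule-based stage classifier from cell proportions
#'
#' Baseline classifier used for fast evaluation-machinery testing: assigns
#' the stage whose configured mixture mean is nearest (Euclidean) to the
#' record's (leukocyte, cornified, nucleated) proportions — the classical
#' cell-counting approach to staging.
#'
#' @param m An `estrous_manifest` with proportion columns.
#' @param mix A [stage_mixture()].
#' @return Character vector of predicted stages.
#' @export
classify_by_proportions <- function(m, mix = stage_mixture()) {
  p <- as.matrix(as.data.frame(m)[, c("leukocyte_frac", "cornified_frac",
                                      "nucleated_frac")])
  vapply(seq_len(nrow(p)), function(i) {
    d <- colSums((t(mix$means) - p[i, ])^2)
    canonical_stages()[which.min(d)]
  }, character(1))
}

#' Full evaluation report
#'
#' Convenience wrapper bundling the confusion matrix, per-stage one-vs-rest
#' ROC/auROC, and a bootstrap accuracy distribution for one set of
#' classifications.
#'
#' @param truth True stage labels.
#' @param pred Predicted stage labels.
#' @param scores Optional samples x stages probability matrix (column names =
#'   stages) enabling the ROC section.
#' @param n_boot Bootstrap iterations (default 5000).
#' @param seed Integer seed.
#' @return List with `confusion`, `roc` (per stage, when scores given),
#'   `bootstrap`.
#' @export
evaluation_report <- function(truth, pred, scores = NULL, n_boot = 5000,
                              seed = NULL) {
  out <- list(confusion = confusion_matrix(truth, pred))
  if (!is.null(scores)) {
    out$roc <- lapply(stats::setNames(nm = colnames(scores)), function(s) {
      if (length(unique(truth == s)) < 2) return(NULL)
      one_vs_rest_roc(scores, truth, s)
    })
    out$auroc <- vapply(out$roc, function(r) r$auroc %||% NA_real_, numeric(1))
  }
  out$bootstrap <- bootstrap_accuracy(truth, pred, n_iter = n_boot, seed = seed)
  out
}
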