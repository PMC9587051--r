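test_that("confusion matrices count, normalise and score as defined", {
  truth <- rep(canonical_stages(), each = 3)
  cm <- confusion_matrix(truth, truth)
  expect_equal(unname(diag(cm$counts)), rep(3, 4))
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0)
  expect_equal(cm$accuracy, 1)
  cm2 <- confusion_matrix(rep("diestrus", 5), rep("proestrus", 5))
  expect_equal(cm2$counts["diestrus", "proestrus"], 5)
  expect_equal(sum(cm2$counts), 5)
  expect_equal(cm2$accuracy, 0)
  # row-normalised rows sum to 1 (rows with data)
  mixed <- confusion_matrix(truth, sample(truth))
  expect_equal(unname(rowSums(mixed$normalized)), rep(1, 4))
  expect_equal(sum(mixed$counts), length(truth))
  expect_error(confusion_matrix("diestrus", "anestrus"), "outside")
})

test_that("one-vs-rest ROC spans (0,0) to (1,1) and handles separation and inversion", {
  truth <- rep(c("estrus", "diestrus"), each = 4)
  perfect <- c(0.9, 0.8, 0.85, 0.7, 0.2, 0.1, 0.3, 0.05)
  roc <- one_vs_rest_roc(perfect, truth, "estrus")
  expect_equal(roc$auroc, 1.0)
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[length(roc$fpr)], roc$tpr[length(roc$tpr)]), c(1, 1))
  inv <- one_vs_rest_roc(1 - perfect, truth, "estrus")
  expect_equal(inv$auroc, 1 - roc$auroc)
  # 4-sample worked example: wins 3 of 4 positive-negative pairs
  r4 <- one_vs_rest_roc(c(0.9, 0.8, 0.4, 0.1),
                        c("estrus", "diestrus", "estrus", "diestrus"), "estrus")
  expect_equal(r4$auroc, 0.75)
  expect_error(one_vs_rest_roc(runif(4), rep("estrus", 4), "estrus"), "both classes")
})

test_that("trapezoidal auROC equals the pairwise win fraction and matches pROC", {
  pairwise_auc <- function(scores, pos) {
    s_p <- scores[pos]; s_n <- scores[!pos]
    wins <- outer(s_p, s_n, function(a, b) (a > b) + 0.5 * (a == b))
    mean(wins)
  }
  set.seed(5)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    truth <- sample(c("estrus", "diestrus"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- round(runif(n), 2)  # ties likely
    r <- one_vs_rest_roc(scores, truth, "estrus")
    expect_equal(r$auroc, pairwise_auc(scores, truth == "estrus"),
                 tolerance = 1e-12)
  }
  # independent library cross-check on one instance
  if (requireNamespace("pROC", quietly = TRUE)) {
    truth <- sample(c("estrus", "diestrus"), 40, replace = TRUE)
    scores <- runif(40)
    r <- one_vs_rest_roc(scores, truth, "estrus")
    expect_equal(r$auroc,
                 as.numeric(pROC::auc(pROC::roc(truth == "estrus", scores,
                                                quiet = TRUE, direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("sensitivity/specificity curves cross where a dense grid says they do", {
  pos_scores <- c(0.6, 0.7, 0.8)
  neg_scores <- c(0.4, 0.3, 0.2)
  ss <- sens_spec_cutoff(c(pos_scores, neg_scores),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(ss$cutoff, 0.5, tolerance = 1e-9)  # symmetric around 0.5
  expect_equal(ss$sensitivity[ss$thresholds == 0], 1)
  expect_equal(ss$specificity[ss$thresholds == 1], 1)
  set.seed(8)
  scores <- c(runif(30, 0.3, 1), runif(30, 0, 0.7))
  truth <- rep(c(TRUE, FALSE), each = 30)
  ss2 <- sens_spec_cutoff(scores, truth)
  # dense-grid oracle: minimize |sens - spec| over a 1e-4 threshold grid
  grid <- seq(0, 1, by = 1e-4)
  dd <- vapply(grid, function(t) {
    abs(mean(scores[truth] >= t) - mean(scores[!truth] <= t))
  }, numeric(1))
  # within one data-driven grid step of the dense minimiser
  expect_lt(abs(ss2$cutoff - grid[which.min(dd)]), 0.05)
})

test_that("bootstrap accuracy is seeded, unbiased, and degenerates correctly", {
  truth <- rep(canonical_stages(), each = 10)
  b0 <- bootstrap_accuracy(truth, truth, n_iter = 200, seed = 1)
  expect_true(all(b0$accuracies == 1))
  set.seed(3)
  pred <- ifelse(runif(40) < 0.3, "diestrus", truth)
  b1 <- bootstrap_accuracy(truth, pred, n_iter = 5000, seed = 2)
  b2 <- bootstrap_accuracy(truth, pred, n_iter = 5000, seed = 2)
  expect_identical(b1$accuracies, b2$accuracies)
  point <- mean(truth == pred)
  mc_se <- sd(b1$accuracies) / sqrt(5000) + sqrt(point * (1 - point) / 40) / sqrt(5000)
  # bootstrap mean within 2 SE-of-the-point-estimate of the point accuracy
  expect_lt(abs(b1$mean - point), 2 * sqrt(point * (1 - point) / 40))
  expect_equal(b1$bar_lower, b1$q25 - b1$iqr)
  expect_equal(b1$bar_upper, b1$q75 + b1$iqr)
})

test_that("Fisher's exact comparison reports the sample OR, Woolf CI and exact p", {
  same <- fisher_exact_comparison(5, 10, 5, 10)
  expect_equal(same$odds_ratio, 1.0)
  expect_equal(same$p_value, 1.0)
  # OR of [[8,2],[4,6]] = (8*6)/(2*4)
  or6 <- fisher_exact_comparison(8, 10, 4, 10)
  expect_equal(or6$odds_ratio, 6.0)
  expect_true(or6$conf_int[1] < 6 && or6$conf_int[2] > 6)
  # extreme table: p equals the enumerated two-sided hypergeometric tail
  ext <- fisher_exact_comparison(10, 10, 0, 10)
  k <- 10; m1 <- 10; m2 <- 10
  probs <- dhyper(0:10, m1, m2, k)
  p_oracle <- sum(probs[probs <= dhyper(10, m1, m2, k) * (1 + 1e-7)])
  expect_equal(ext$p_value, p_oracle, tolerance = 1e-12)
  # p is symmetric in the two groups
  a <- fisher_exact_comparison(7, 12, 3, 9)
  b <- fisher_exact_comparison(3, 9, 7, 12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_gt(a$p_value, 0); expect_lte(a$p_value, 1)
  expect_error(fisher_exact_comparison(1, 0, 1, 2), "non-empty")
})

test_that("grouped k-fold partitions groups without leakage and averages folds", {
  m <- make_test_manifest(12)            # 48 records, 4 subjects
  m$subject_id <- sprintf("subj%02d", rep_len(1:12, nrow(m)))
  m <- as_manifest(as.data.frame(m))
  res <- grouped_kfold_oos(m, "subject_id", k = 6, trainer = proportion_trainer,
                           seed = 1)
  expect_length(res$fold_accuracy, 6)
  expect_equal(res$mean_accuracy, mean(res$fold_accuracy))
  expect_equal(unname(vapply(res$folds, length, 1L)), rep(2L, 6))  # 12 subjects, k=6
  for (fold in res$folds) {
    test_idx <- m$subject_id %in% fold
    expect_equal(length(intersect(m$subject_id[test_idx], m$subject_id[!test_idx])), 0)
  }
  expect_error(grouped_kfold_oos(m, "species", k = 6, trainer = proportion_trainer),
               "smaller k")
})

test_that("leave-one-category-out removes each stain entirely from training", {
  m <- make_test_manifest(10, stains = c("HE", "Shorr", "Giemsa",
                                         "CresylViolet", "CrystalViolet"))
  seen <- character(0)
  spy_trainer <- function(train_m, test_m) {
    expect_equal(length(intersect(unique(train_m$stain), unique(test_m$stain))), 0)
    expect_length(unique(test_m$stain), 1)
    seen <<- c(seen, unique(test_m$stain))
    proportion_trainer(train_m, test_m)
  }
  res <- grouped_kfold_oos(m, "stain", trainer = spy_trainer,
                           mode = "leave_one_out")
  expect_length(res$fold_accuracy, 5)
  expect_setequal(seen, unique(m$stain))
})
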