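# cheaper forest settings keep the suite fast; behavior, not precision,
# is under test here
fast_rf <- function(seed = 1) rf_config(n_trees = 300, n_repeats = 2,
                                        seed = seed)

test_that("OOB error is near zero for a cleanly separating feature", {
  errs <- vapply(1:5, function(s) {
    set.seed(s)
    lab <- toy_labels(8)
    m <- sim_matrix(1, lab, n_shift = 1, effect = 6, noise_sd = 0.5,
                    prefix = "L")
    oob_error(m, lab, config = fast_rf(s))
  }, numeric(1))
  expect_lte(mean(errs), 0.1)
})

test_that("OOB error sits near 0.5 under permuted labels / pure noise", {
  errs <- vapply(1:25, function(s) {
    set.seed(s)
    lab <- toy_labels(10)
    m <- sim_matrix(8, lab, prefix = "L")   # pure noise features
    oob_error(m, lab, config = fast_rf(s))
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.15)
})

test_that("OOB error is deterministic given a seed and validates input", {
  set.seed(3)
  lab <- toy_labels(5)
  m <- sim_matrix(4, lab, prefix = "L")
  e1 <- oob_error(m, lab, config = fast_rf(9))
  e2 <- oob_error(m, lab, config = fast_rf(9))
  expect_identical(e1, e2)
  expect_error(oob_error(m, lab, features = "absent"), "absent")
})

test_that("singleton candidate set selects itself with a one-point trace", {
  set.seed(4)
  lab <- toy_labels(5)
  m <- sim_matrix(1, lab, n_shift = 1, effect = 3, prefix = "L")
  pan <- select_biomarkers(m, lab, config = fast_rf())
  expect_identical(pan$selected, "L001")
  expect_identical(nrow(pan$oob_trace), 1L)
})

test_that("the selected panel size minimizes the OOB trace, ties smallest", {
  set.seed(5)
  lab <- toy_labels(8)
  m <- sim_matrix(12, lab, n_shift = 3, effect = 2, prefix = "L")
  pan <- select_biomarkers(m, lab, config = fast_rf(2))
  k <- length(pan$selected)
  expect_equal(pan$oob_trace$oob_error[k], min(pan$oob_trace$oob_error))
  expect_false(any(pan$oob_trace$oob_error[seq_len(k - 1)] <=
                     pan$oob_trace$oob_error[k]))
  expect_identical(pan$selected, names(pan$importance)[seq_len(k)])
  expect_error(select_biomarkers(m, lab, candidates = character(0)), "empty")
})

test_that("LOOCV emits one record per sample and flags degenerate folds", {
  set.seed(6)
  lab <- toy_labels(2)                      # n = 4 minimal run
  m <- sim_matrix(3, lab, prefix = "L")
  preds <- loocv_evaluate(m, lab, rownames(m), config = fast_rf())
  expect_identical(nrow(preds), 4L)
  expect_setequal(preds$sample_id, names(lab))
  expect_true(all(preds$score >= 0 & preds$score <= 1))

  lab1 <- group_labels(c("A", "B", "C"),
                       c("high_BMD", "low_BMD", "low_BMD"))
  m1 <- expr_matrix(matrix(rnorm(3), 1, 3,
                           dimnames = list("L1", c("A", "B", "C"))), "lncRNA")
  expect_error(loocv_evaluate(m1, lab1, "L1"), ">= 2 samples per group")
})

test_that("LOOCV separates a strongly coupled dataset perfectly", {
  set.seed(17)
  lab <- toy_labels(5)
  m <- sim_matrix(10, lab, n_shift = 5, effect = 4, noise_sd = 0.5,
                  prefix = "L")
  preds <- loocv_evaluate(m, lab, rownames(m)[1:5], config = fast_rf())
  expect_true(all(preds$score[preds$true_group == "low_BMD"] > 0.5))
  expect_true(all(preds$score[preds$true_group == "high_BMD"] < 0.5))
  expect_equal(roc_and_auc(preds)$auc, 1.0)
})

test_that("LOOCV is well-calibrated to chance under permuted labels", {
  aucs <- vapply(1:8, function(s) {
    set.seed(s)
    lab <- toy_labels(5)
    m <- sim_matrix(6, lab, prefix = "L")   # labels carry no signal
    roc_and_auc(loocv_evaluate(m, lab, rownames(m),
                               config = fast_rf(s)))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.2)
})

test_that("ROC/AUC agree with hand values and the pair-counting oracle", {
  perfect <- prediction_frame(c(0.9, 0.8), c(0.2, 0.1))
  expect_equal(roc_and_auc(perfect)$auc, 1.0)

  flat <- prediction_frame(c(0.4, 0.4), c(0.4, 0.4))
  expect_warning(res <- roc_and_auc(flat), "identical")
  expect_equal(res$auc, 0.5)
  expect_true(res$degenerate)

  # 6 scores with one tie: brute-force over all case-control pairs,
  # ties counted 1/2
  preds <- prediction_frame(c(0.9, 0.5, 0.3), c(0.5, 0.2, 0.1))
  pos <- c(0.9, 0.5, 0.3); neg <- c(0.5, 0.2, 0.1)
  wins <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
  expect_equal(roc_and_auc(preds)$auc, wins / 9)
})

test_that("trapezoid AUC equals tie-corrected Mann-Whitney on random sets", {
  set.seed(31)
  for (i in 1:50) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    # coarse grid forces frequent ties
    pos <- sample(seq(0, 1, 0.25), n1, replace = TRUE)
    neg <- sample(seq(0, 1, 0.25), n2, replace = TRUE)
    preds <- prediction_frame(pos, neg)
    wins <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
    got <- suppressWarnings(roc_and_auc(preds))
    expect_equal(got$auc, wins / (n1 * n2), tolerance = 1e-12)
    # ROC monotone from (0,0) to (1,1)
    expect_equal(got$roc$fpr[1], 0); expect_equal(got$roc$tpr[1], 0)
    expect_equal(got$roc$fpr[nrow(got$roc)], 1)
    expect_true(all(diff(got$roc$fpr) >= 0))
    expect_true(all(diff(got$roc$tpr) >= 0))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(32)
  preds <- prediction_frame(runif(6), runif(5))
  base <- roc_and_auc(preds)$auc
  trans <- preds
  trans$score <- plogis(3 * preds$score - 1)
  expect_equal(roc_and_auc(trans)$auc, base, tolerance = 1e-12)
})

test_that("confusion_metrics reproduces the printed cohort accuracies", {
  # 11 of 15 low-BMD and 9 of 16 high-BMD correct -> accuracy 64.5%
  preds <- prediction_frame(c(rep(0.9, 11), rep(0.1, 4)),
                            c(rep(0.1, 9), rep(0.9, 7)))
  cm <- confusion_metrics(preds)
  expect_identical(c(cm$tp, cm$fn, cm$tn, cm$fp), c(11L, 4L, 9L, 7L))
  expect_equal(round(100 * cm$accuracy, 1), 64.5)
  expect_equal(cm$sensitivity, 11 / 15)
  expect_equal(cm$specificity, 9 / 16)

  # 7 of 10 and 7 of 10 -> 70%
  preds2 <- prediction_frame(c(rep(0.9, 7), rep(0.1, 3)),
                             c(rep(0.1, 7), rep(0.9, 3)))
  expect_equal(confusion_metrics(preds2)$accuracy, 0.70)

  perfect <- prediction_frame(c(0.8, 0.9), c(0.1, 0.2))
  cmp <- confusion_metrics(perfect)
  expect_equal(c(cmp$accuracy, cmp$sensitivity, cmp$specificity), c(1, 1, 1))
  expect_error(confusion_metrics(perfect, threshold = 2), "threshold")
})

test_that("auc_ci matches the closed-form Hanley-McNeil oracle", {
  preds <- prediction_frame(c(0.9, 0.7, 0.6, 0.4), c(0.5, 0.3, 0.2))
  a <- roc_and_auc(preds)$auc
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + 3 * (q1 - a^2) + 2 * (q2 - a^2)) / 12)
  ci <- auc_ci(preds, method = "hanley_mcneil")
  expect_equal(ci$lower, max(0, a - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(ci$upper, min(1, a + qnorm(0.975) * se), tolerance = 1e-12)

  # clear separation: bootstrap upper bound pinned at 1
  sep <- prediction_frame(c(0.9, 0.95, 0.85), c(0.1, 0.2, 0.15))
  ci2 <- auc_ci(sep, n_boot = 200, seed = 5)
  expect_equal(ci2$upper, 1.0)
  expect_true(ci2$lower <= ci2$auc && ci2$auc <= ci2$upper)
  expect_error(auc_ci(prediction_frame(0.5, c(0.1, 0.2)), n_boot = 10),
               ">= 2")
})

test_that("intersect_panel restricts in order and rejects empty overlap", {
  pan <- c("a", "b", "c", "d")
  expect_identical(intersect_panel(pan, c("d", "b")), c("b", "d"))
  expect_identical(intersect_panel(pan, pan), pan)
  expect_error(intersect_panel(pan, "zzz"), "covered")
})

test_that("fixed seeds give byte-identical LOOCV reports", {
  set.seed(8)
  lab <- toy_labels(4)
  m <- sim_matrix(5, lab, n_shift = 2, effect = 2, prefix = "L")
  p1 <- loocv_evaluate(m, lab, rownames(m), config = fast_rf(3))
  p2 <- loocv_evaluate(m, lab, rownames(m), config = fast_rf(3))
  expect_identical(p1, p2)
})
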