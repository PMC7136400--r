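#' Select a lncRNA biomarker panel by OOB-error minimization
#'
#' All candidate features are ranked by permutation importance averaged
#' over `n_repeats` forest refits; nested panels (top-1, top-2, ...,
#' top-p) are then scored by out-of-bag error and the panel minimizing the
#' OOB error is selected, ties broken toward the smaller panel. The full
#' (panel size, OOB error) trace is returned so the selection is auditable.
#'
#' @param mat an [expr_matrix()] (typically the lncRNA matrix).
#' @param labels [group_labels()].
#' @param candidates candidate feature ids (e.g., the network lncRNAs);
#'   default all rows of `mat`.
#' @param config an [rf_config()].
#' @return a `biomarker_panel`: list with `selected` (ids, importance
#'   order), `importance` (named, all candidates, descending), `oob_trace`
#'   (data.frame `size`, `oob_error`), `config`.
#' @export
select_biomarkers <- function(mat, labels, candidates = rownames(mat),
                              config = rf_config()) {
  if (length(candidates) == 0) stop("candidate set is empty")
  d <- rf_design(mat, labels, candidates)
  fit <- rf_oob_fit(d$x, d$y, config, importance = TRUE)
  # rank by importance, descending; ties broken by id for determinism
  ord <- order(-fit$importance, names(fit$importance))
  ranked <- names(fit$importance)[ord]
  p <- length(ranked)
  trace <- data.frame(size = seq_len(p), oob_error = NA_real_)
  for (k in seq_len(p)) {
    sub <- rf_config(n_trees = config$n_trees, mtry_rule = config$mtry_rule,
                     n_repeats = config$n_repeats,
                     seed = config$seed + k)
    trace$oob_error[k] <- rf_oob_fit(
      d$x[, ranked[seq_len(k)], drop = FALSE], d$y, sub)$oob_error
  }
  best <- which(trace$oob_error == min(trace$oob_error))[1] # ties -> smallest
  structure(list(selected = ranked[seq_len(best)],
                 importance = fit$importance[ord],
                 oob_trace = trace, config = config),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("biomarker_panel: %d of %d candidates (OOB error %.3f)\n",
              length(x$selected), nrow(x$oob_trace),
              min(x$oob_trace$oob_error)))
  invisible(x)
}

#' Restrict a biomarker panel to the features a platform covers
#'
#' @param panel a `biomarker_panel` or plain character vector of ids.
#' @param available_features ids measurable on the target platform.
#' @return the panel restricted to `available_features`, order preserved.
#'   An empty intersection is an error (nothing left to evaluate).
#' @export
intersect_panel <- function(panel, available_features) {
  ids <- if (inherits(panel, "biomarker_panel")) panel$selected else panel
  kept <- ids[ids %in% available_features]
  if (length(kept) == 0)
    stop("no panel feature is covered by the available features")
  if (inherits(panel, "biomarker_panel")) {
    panel$selected <- kept
    panel$importance <- panel$importance[names(panel$importance) %in% kept]
    panel
  } else kept
}

#' Leave-one-out cross-validated random-forest predictions
#'
#' For each sample, a forest is trained on the remaining n - 1 samples
#' using the fixed panel and the held-out sample's positive-class
#' (low-BMD) vote fraction is recorded. The panel is NOT re-selected
#' inside folds unless `nested = TRUE`, matching the usual (optimistic)
#' evaluate-a-fixed-signature design; nested re-selection gives honest
#' error estimates.
#'
#' @param mat an [expr_matrix()].
#' @param labels [group_labels()].
#' @param panel a `biomarker_panel` or character vector of feature ids.
#' @param config an [rf_config()].
#' @param nested re-run [select_biomarkers()] inside every training fold.
#' @return a data.frame `sample_id`, `true_group`, `score` (positive-class
#'   vote fraction), `predicted` (at threshold 0.5).
#' @export
loocv_evaluate <- function(mat, labels, panel, config = rf_config(),
                           nested = FALSE) {
  ids <- if (inherits(panel, "biomarker_panel")) panel$selected else panel
  d <- rf_design(mat, labels, ids)
  labels <- check_labels(mat, labels)
  n <- nrow(d$x)
  if (min(table(labels)) < 2)
    stop("LOOCV needs >= 2 samples per group so no training fold loses a group")
  scores <- numeric(n)
  seeds <- derive_seeds(config$seed, n)
  mtry_cfg <- config
  for (i in seq_len(n)) {
    tr_idx <- setdiff(seq_len(n), i)
    feats <- ids
    if (nested) {
      sub <- expr_matrix(unclass(mat)[, tr_idx, drop = FALSE],
                         rna_class(mat))
      feats <- select_biomarkers(sub, labels[tr_idx],
                                 candidates = ids, config = config)$selected
    }
    xtr <- d$x[tr_idx, feats, drop = FALSE]
    xte <- d$x[i, feats, drop = FALSE]
    mtry <- resolve_mtry(mtry_cfg, length(feats))
    scores[i] <- .rf_predict_cpp(xtr, d$y[tr_idx], xte,
                                 config$n_trees, mtry, seeds[i])
  }
  data.frame(sample_id = d$samples,
             true_group = as.character(labels),
             score = scores,
             predicted = ifelse(scores >= 0.5, "low_BMD", "high_BMD"),
             stringsAsFactors = FALSE)
}

#' ROC curve and AUC from out-of-fold scores
#'
#' Sweeps all score thresholds to build the ROC polygon and integrates it
#' by the trapezoidal rule; with ties this equals the tie-corrected
#' Mann-Whitney statistic divided by n1*n2.
#'
#' @param predictions data.frame from [loocv_evaluate()] (needs
#'   `true_group`, `score`).
#' @param positive_group group treated as positive (default `"low_BMD"`).
#' @return list with `roc` (data.frame `fpr`, `tpr`, starts at (0,0), ends
#'   at (1,1)), `auc`, and `degenerate` (TRUE when all scores tie).
#' @export
roc_and_auc <- function(predictions, positive_group = "low_BMD") {
  y <- predictions$true_group == positive_group
  s <- predictions$score
  if (!any(y) || all(y)) stop("both groups must be present")
  degenerate <- length(unique(s)) == 1
  if (degenerate)
    warning("all scores identical; ROC is the chance diagonal, AUC = 0.5")
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(s[y] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s[!y] >= t), numeric(1))
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  roc <- unique(roc)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc, degenerate = degenerate)
}

#' Confusion-matrix metrics at a score threshold
#'
#' Predicts positive iff `score >= threshold` and reports accuracy,
#' sensitivity and specificity with the raw confusion counts.
#'
#' @inheritParams roc_and_auc
#' @param threshold score cutoff in \[0, 1\].
#' @return list with `tp`, `fp`, `tn`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity` (proportions in \[0, 1\]).
#' @export
confusion_metrics <- function(predictions, positive_group = "low_BMD",
                              threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  y <- predictions$true_group == positive_group
  pred <- predictions$score >= threshold
  tp <- sum(y & pred); fn <- sum(y & !pred)
  tn <- sum(!y & !pred); fp <- sum(!y & pred)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(y),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Confidence interval for an AUC
#'
#' `"bootstrap"` (default) stratified-resamples the samples within each
#' group and takes the percentile interval of the recomputed AUCs;
#' `"hanley_mcneil"` uses the closed-form standard error
#' \deqn{SE^2 = [A(1-A) + (n_+-1)(Q_1-A^2) + (n_--1)(Q_2-A^2)]/(n_+ n_-)}
#' with \eqn{Q_1 = A/(2-A)}, \eqn{Q_2 = 2A^2/(1+A)}, and a normal interval
#' clipped to \[0, 1\].
#'
#' @inheritParams roc_and_auc
#' @param level confidence level in (0, 1).
#' @param method `"bootstrap"` or `"hanley_mcneil"`.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return list with `auc`, `lower`, `upper`, `method`.
#' @export
auc_ci <- function(predictions, positive_group = "low_BMD", level = 0.95,
                   method = c("bootstrap", "hanley_mcneil"),
                   n_boot = 2000, seed = 1L) {
  method <- match.arg(method)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  point <- roc_and_auc(predictions, positive_group)$auc
  y <- predictions$true_group == positive_group
  n_pos <- sum(y); n_neg <- sum(!y)
  if (method == "hanley_mcneil") {
    a <- point
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) +
                  (n_neg - 1) * (q2 - a^2)) / (n_pos * n_neg))
    zq <- stats::qnorm(1 - (1 - level) / 2)
    return(list(auc = a, lower = max(0, a - zq * se),
                upper = min(1, a + zq * se), method = "hanley_mcneil"))
  }
  if (n_pos < 2 || n_neg < 2)
    stop("each group needs >= 2 samples for stratified bootstrap")
  set.seed(seed)
  pos_i <- which(y); neg_i <- which(!y)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(pos_i, n_pos, replace = TRUE),
             sample(neg_i, n_neg, replace = TRUE))
    suppressWarnings(
      roc_and_auc(predictions[idx, , drop = FALSE], positive_group)$auc)
  }, numeric(1))
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(auc = point, lower = qs[1], upper = qs[2], method = "bootstrap")
}
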