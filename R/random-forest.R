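#' Random-forest configuration
#'
#' Hyperparameters for the bundled random-forest classifier used in
#' biomarker selection and LOOCV evaluation.
#'
#' @param n_trees trees per forest (default 1000).
#' @param mtry_rule feature-subsample rule; `"sqrt"` (default) uses
#'   `floor(sqrt(p))`, or give a fixed positive integer.
#' @param n_repeats forest refits averaged for importance / OOB stability.
#' @param seed integer RNG seed.
#' @return an `rf_config` list.
#' @export
rf_config <- function(n_trees = 1000, mtry_rule = "sqrt",
                      n_repeats = 10, seed = 1L) {
  if (n_trees < 1) stop("`n_trees` must be >= 1")
  if (n_repeats < 1) stop("`n_repeats` must be >= 1")
  if (!identical(mtry_rule, "sqrt") &&
      (!is.numeric(mtry_rule) || mtry_rule < 1))
    stop("`mtry_rule` must be \"sqrt\" or a positive integer")
  structure(list(n_trees = as.integer(n_trees), mtry_rule = mtry_rule,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "rf_config")
}

resolve_mtry <- function(config, p) {
  m <- if (identical(config$mtry_rule, "sqrt")) floor(sqrt(p))
       else as.integer(config$mtry_rule)
  max(1L, min(as.integer(m), p))
}

# samples x features matrix + 0/1 labels (1 = low_BMD, the positive class)
rf_design <- function(mat, labels, features) {
  labels <- check_labels(mat, labels)
  miss <- setdiff(features, rownames(mat))
  if (length(miss))
    stop("feature(s) absent from matrix: ", paste(miss, collapse = ", "))
  if (length(features) == 0) stop("need >= 1 feature")
  x <- t(unclass(mat)[features, , drop = FALSE])
  y <- as.integer(labels == "low_BMD")
  if (length(unique(y)) < 2) stop("both groups must be present")
  list(x = x, y = y, samples = colnames(mat))
}

# deterministic per-repeat seed stream below 2^31
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% 2147483629 + 1
}

rf_oob_fit <- function(x, y, config, importance = FALSE) {
  mtry <- resolve_mtry(config, ncol(x))
  seeds <- derive_seeds(config$seed, config$n_repeats)
  errs <- numeric(config$n_repeats)
  imp <- matrix(0, config$n_repeats, ncol(x))
  votes <- matrix(0, config$n_repeats, nrow(x))
  for (i in seq_len(config$n_repeats)) {
    fit <- .rf_oob_cpp(x, y, config$n_trees, mtry, seeds[i], importance)
    errs[i] <- fit$oob_error
    imp[i, ] <- fit$importance
    votes[i, ] <- fit$oob_votes
  }
  list(oob_error = mean(errs),
       importance = stats::setNames(colMeans(imp), colnames(x)),
       oob_votes = stats::setNames(colMeans(votes), rownames(x)))
}

#' Out-of-bag error of a random forest on a feature panel
#'
#' Fits `n_repeats` forests on the given features and returns the mean
#' fraction of samples misclassified by the trees whose bootstrap samples
#' excluded them.
#'
#' @param mat an [expr_matrix()].
#' @param labels [group_labels()].
#' @param features feature (gene) ids; must exist in `mat`.
#' @param config an [rf_config()].
#' @return OOB misclassification rate in \[0, 1\].
#' @export
oob_error <- function(mat, labels, features = rownames(mat),
                      config = rf_config()) {
  d <- rf_design(mat, labels, features)
  rf_oob_fit(d$x, d$y, config)$oob_error
}
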