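#' Moderated two-sample t-test per gene
#'
#' Empirical-Bayes moderated t for a two-group comparison: each gene's
#' pooled variance \eqn{s_g^2} (on \eqn{d = n_1 + n_2 - 2} df) is shrunk
#' toward a prior \eqn{s_0^2} with weight \eqn{d_0} prior df,
#' \deqn{\tilde s_g^2 = (d_0 s_0^2 + d s_g^2) / (d_0 + d),}
#' and the t statistic uses \eqn{\tilde s_g} with \eqn{d_0 + d} df. The
#' prior \eqn{(d_0, s_0^2)} is estimated by moment matching on the
#' log-variance distribution (digamma/trigamma identities, trigamma solved
#' by Newton iteration), the standard shrinkage construction for microarray
#' data. `prior_df = 0` degenerates to the ordinary pooled two-sample t;
#' `prior_df = Inf` replaces every variance by the across-gene mean pooled
#' variance.
#'
#' The log2 fold change is `mean_high - mean_low`, so direction `"up"`
#' means higher expression in the high-BMD group.
#'
#' @param mat an [expr_matrix()].
#' @param labels [group_labels()] covering exactly the matrix samples.
#' @param prior_df `NULL` (estimate from the data), `0`, `Inf`, or a fixed
#'   non-negative prior df.
#' @return a data.frame with one row per gene: `gene_id`, `rna_class`,
#'   `mean_high`, `mean_low`, `log2fc`, `direction`, `t_stat`, `df`,
#'   `p_value`, `q_value` (BH), ordered by `p_value` then id.
#' @export
moderated_t_test <- function(mat, labels, prior_df = NULL) {
  labels <- check_labels(mat, labels)
  hi <- names(labels)[labels == "high_BMD"]
  lo <- names(labels)[labels == "low_BMD"]
  if (length(hi) < 2 || length(lo) < 2)
    stop("each group needs >= 2 samples")
  x <- unclass(mat)
  n1 <- length(hi); n2 <- length(lo)
  m1 <- rowMeans(x[, hi, drop = FALSE])
  m2 <- rowMeans(x[, lo, drop = FALSE])
  ss1 <- rowSums((x[, hi, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, lo, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d

  if (is.null(prior_df)) {
    pr <- fit_variance_prior(s2, d)
    d0 <- pr$d0; s02 <- pr$s02
  } else if (prior_df == 0) {
    d0 <- 0; s02 <- 0
  } else if (is.infinite(prior_df)) {
    d0 <- Inf; s02 <- mean(s2)
  } else {
    if (prior_df < 0) stop("`prior_df` must be >= 0")
    d0 <- prior_df
    s02 <- mean(s2)
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + d * s2) / (d0 + d)
  df_total <- if (is.infinite(d0)) Inf else d0 + d

  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  lfc <- m1 - m2
  t_stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  p[se == 0] <- 1
  out <- data.frame(
    gene_id = rownames(x), rna_class = rna_class(mat),
    mean_high = m1, mean_low = m2, log2fc = lfc,
    direction = ifelse(lfc >= 0, "up", "down"),
    t_stat = t_stat, df = df_total, p_value = p,
    q_value = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value, out$gene_id), , drop = FALSE]
}

# moment matching of a scaled-F / log-chisq model to the observed log s^2:
#   E[log s2] = log s02 + digamma(d/2) - digamma(d0/2) + log(d0/d)
#   Var[log s2] = trigamma(d/2) + trigamma(d0/2)
fit_variance_prior <- function(s2, d) {
  pos <- s2[s2 > 0]
  if (length(pos) < 2) return(list(d0 = Inf, s02 = mean(s2)))
  z <- log(pos)
  excess <- stats::var(z) - trigamma(d / 2)
  if (!is.finite(excess) || excess <= 0) {
    # observed spread no wider than sampling noise: infinite shrinkage
    s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
    return(list(d0 = Inf, s02 = s02))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s02 <- exp(mean(z) + digamma(d0 / 2) - digamma(d / 2) - log(d0 / d))
  list(d0 = d0, s02 = s02)
}

# solve trigamma(y) = x for y > 0 by Newton on the inverse scale
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Filter a differential-expression table at a raw p-value cutoff
#'
#' Keeps records with `p_value < alpha` (strict inequality on the raw,
#' unadjusted p-value). Set `use_q = TRUE` to filter on the BH q-value
#' instead.
#'
#' @param records output of [moderated_t_test()].
#' @param alpha significance cutoff in (0, 1].
#' @param use_q filter on `q_value` instead of `p_value`.
#' @return the retained rows.
#' @export
filter_de <- function(records, alpha = 0.05, use_q = FALSE) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]")
  col <- if (use_q) records$q_value else records$p_value
  records[col < alpha, , drop = FALSE]
}

#' Hierarchical clustering of samples over a gene set
#'
#' Samples are clustered with average linkage on the 1 - Pearson
#' correlation distance computed over the supplied genes, cut into two
#' clusters, and scored for agreement with the phenotype groups
#' (maximum over the two label assignments).
#'
#' @param mat an [expr_matrix()].
#' @param labels [group_labels()] for the matrix samples.
#' @param genes gene ids to cluster on; default all rows.
#' @return list with `hclust` (the tree), `clusters` (named integer vector,
#'   values 1/2) and `agreement` in \[0.5, 1\].
#' @export
hierarchical_cluster <- function(mat, labels, genes = rownames(mat)) {
  labels <- check_labels(mat, labels)
  if (ncol(mat) < 2) stop("need >= 2 samples")
  missing_g <- setdiff(genes, rownames(mat))
  if (length(missing_g))
    stop("gene(s) absent from matrix: ", paste(missing_g, collapse = ", "))
  x <- unclass(mat)[genes, , drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (all(apply(x, 1, stats::sd) == 0))
    stop("all selected genes are constant; correlation distance undefined")
  cc <- suppressWarnings(stats::cor(x))
  if (anyNA(cc))
    stop("constant sample profile; correlation distance undefined")
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  cl <- stats::cutree(hc, k = 2)
  ref <- as.integer(labels == "low_BMD") + 1L
  agree <- max(mean(cl == ref), mean(cl == (3L - ref)))
  list(hclust = hc, clusters = cl, agreement = agree)
}
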