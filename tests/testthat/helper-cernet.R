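# shared fixture builders; everything is generated in code, no data files

toy_matrix <- function(values, genes, samples, class = "mRNA") {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  expr_matrix(m, class)
}

toy_labels <- function(n_per_group = 2) {
  n <- 2 * n_per_group
  group_labels(sprintf("S%02d", seq_len(n)),
               rep(c("high_BMD", "low_BMD"), each = n_per_group))
}

# random matrix with optional group shift on the first n_shift genes
sim_matrix <- function(n_genes, labels, class = "mRNA", n_shift = 0,
                       effect = 0, noise_sd = 1, prefix = "G") {
  n <- length(labels)
  x <- matrix(stats::rnorm(n_genes * n, mean = 8, sd = noise_sd), n_genes, n,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                              names(labels)))
  if (n_shift > 0)
    x[seq_len(n_shift), labels == "low_BMD"] <-
      x[seq_len(n_shift), labels == "low_BMD"] + effect
  expr_matrix(x, class)
}

prediction_frame <- function(scores_pos, scores_neg) {
  data.frame(
    sample_id = sprintf("S%02d", seq_len(length(scores_pos) + length(scores_neg))),
    true_group = rep(c("low_BMD", "high_BMD"),
                     c(length(scores_pos), length(scores_neg))),
    score = c(scores_pos, scores_neg),
    stringsAsFactors = FALSE)
}

# independent brute-force oracle for the mediation filter: enumerate every
# (lncRNA, mRNA, miRNA) combination and re-check all conditions from the
# raw matrices and the interaction table
oracle_triplets <- function(lnc, mrna, mir, de_l, de_m, de_i, inter,
                            pcc_threshold = 0.5, neg_threshold = 0) {
  pairs_key <- paste(inter$mirna_id, inter$target_id, inter$target_class)
  out <- list()
  for (l in de_l) for (m in de_m) {
    r_lm <- stats::cor(unclass(lnc)[l, ], unclass(mrna)[m, ])
    if (is.na(r_lm) || !(r_lm > pcc_threshold)) next
    for (i in de_i) {
      if (!(paste(i, m, "mRNA") %in% pairs_key)) next
      if (!(paste(i, l, "lncRNA") %in% pairs_key)) next
      r_im <- stats::cor(unclass(mir)[i, ], unclass(mrna)[m, ])
      r_il <- stats::cor(unclass(mir)[i, ], unclass(lnc)[l, ])
      if (is.na(r_im) || is.na(r_il)) next
      if (r_im < neg_threshold && r_il < neg_threshold)
        out[[length(out) + 1]] <- data.frame(
          lncrna_id = l, mrna_id = m, mirna_id = i,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      mirna_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

triplet_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(df$lncrna_id, df$mrna_id, df$mirna_id))
}

# run the package mediation path end to end on a dataset
pipeline_triplets <- function(ds, de_alpha = 0.05, pcc_threshold = 0.5,
                              neg_threshold = 0) {
  de <- lapply(list(mRNA = ds$mrna, lncRNA = ds$lncrna, miRNA = ds$mirna),
               function(m) filter_de(moderated_t_test(m, ds$labels),
                                     alpha = de_alpha))
  if (nrow(de$lncRNA) == 0 || nrow(de$mRNA) == 0 || nrow(de$miRNA) == 0)
    return(list(triplets = data.frame(lncrna_id = character(),
                                      mrna_id = character(),
                                      mirna_id = character()), de = de))
  corr_lm <- pairwise_pcc(ds$lncrna, ds$mrna, de$lncRNA$gene_id,
                          de$mRNA$gene_id)
  cand <- candidate_pairs(corr_lm, pcc_threshold)
  corr_im <- pairwise_pcc(ds$mirna, ds$mrna, de$miRNA$gene_id,
                          de$mRNA$gene_id)
  corr_il <- pairwise_pcc(ds$mirna, ds$lncrna, de$miRNA$gene_id,
                          de$lncRNA$gene_id)
  list(triplets = mediation_filter(cand, ds$interactions, corr_im, corr_il,
                                   de$miRNA$gene_id, neg_threshold),
       de = de)
}
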