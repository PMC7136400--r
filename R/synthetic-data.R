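#' Configuration for the synthetic ceRNA dataset generator
#'
#' Defaults emulate a small two-group microarray study (5 vs 5 subjects)
#' with RNA-class sizes scaled down from genome scale while keeping the
#' miRNA-target interaction space sparse. All expression is on the log2
#' scale.
#'
#' @param n_per_group samples per phenotype group (>= 3).
#' @param n_mrna,n_lncrna,n_mirna gene counts per RNA class.
#' @param n_de_per_class planted differentially expressed genes per class.
#' @param de_effect mean log2 group shift for planted DE genes.
#' @param n_triplets planted ceRNA triplets (<= n_de_per_class; the members
#'   of every planted triplet are drawn from the planted DE genes).
#' @param coupling latent-factor loading in `[0, 1]` controlling triplet
#'   correlation strength; expected within-triplet correlation magnitude is
#'   roughly `coupling^2 / (coupling^2 + noise_sd^2)`.
#' @param n_decoy_interactions random non-functional miRNA-target pairs.
#' @param noise_sd residual standard deviation (log2 units, > 0).
#' @param seed RNG seed (integer).
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(n_per_group = 5,
                         n_mrna = 300, n_lncrna = 200, n_mirna = 60,
                         n_de_per_class = 20, de_effect = 2,
                         n_triplets = 10, coupling = 0.8,
                         n_decoy_interactions = 200,
                         noise_sd = 0.5, seed = 1L) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_mrna = as.integer(n_mrna),
              n_lncrna = as.integer(n_lncrna),
              n_mirna = as.integer(n_mirna),
              n_de_per_class = as.integer(n_de_per_class),
              de_effect = de_effect,
              n_triplets = as.integer(n_triplets), coupling = coupling,
              n_decoy_interactions = as.integer(n_decoy_interactions),
              noise_sd = noise_sd, seed = as.integer(seed))
  counts <- cfg[c("n_mrna", "n_lncrna", "n_mirna", "n_de_per_class",
                  "n_triplets", "n_decoy_interactions")]
  for (nm in names(counts))
    if (counts[[nm]] < 0) stop("`", nm, "` must be >= 0")
  if (cfg$n_per_group < 3)
    stop("`n_per_group` must be >= 3 (correlation needs >= 3 points)")
  if (cfg$coupling < 0 || cfg$coupling > 1)
    stop("`coupling` must be in [0, 1]")
  if (cfg$noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (cfg$n_triplets > min(cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna))
    stop("`n_triplets` must be <= min(n_mrna, n_lncrna, n_mirna)")
  if (cfg$n_triplets > 0 && cfg$n_triplets > cfg$n_de_per_class)
    stop("`n_triplets` must be <= n_de_per_class ",
         "(every planted triplet member must be differentially expressed)")
  if (cfg$n_de_per_class > min(cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna))
    stop("`n_de_per_class` must be <= min(n_mrna, n_lncrna, n_mirna)")
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a paired three-class expression dataset with planted truth
#'
#' Simulates matched mRNA / lncRNA / miRNA log2 expression profiles over two
#' phenotype groups. Planted DE genes get a `de_effect` group-mean shift;
#' each planted ceRNA triplet shares one standard-normal latent factor per
#' sample with loadings `(+coupling, +coupling, -coupling)` on its
#' (mRNA, lncRNA, miRNA), producing the sign pattern the mediation filter
#' tests: positive lncRNA-mRNA and negative miRNA-mRNA / miRNA-lncRNA
#' correlation. Within a triplet the mRNA and lncRNA share a DE direction
#' and the miRNA takes the opposite one. The emitted interaction table holds
#' both targeting pairs of every planted triplet plus uniformly drawn decoy
#' pairs that never coincide with planted pairs.
#'
#' @param config a [synth_config()].
#' @return a `synthetic_dataset` list with elements `mrna`, `lncrna`,
#'   `mirna` ([expr_matrix()]s over identical samples), `labels`
#'   ([group_labels()]), `interactions` ([interaction_table()]) and `truth`
#'   (list of `de_genes`, `triplets`, `functional_interactions`).
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- 2L * config$n_per_group
  samples <- sprintf("S%02d", seq_len(n))
  groups <- rep(c("high_BMD", "low_BMD"), each = config$n_per_group)
  labels <- group_labels(samples, groups)
  gsign <- ifelse(groups == "high_BMD", 0.5, -0.5)  # "up" = higher in high_BMD

  ids <- list(mRNA = sprintf("MRNA%04d", seq_len(config$n_mrna)),
              lncRNA = sprintf("LNC%04d", seq_len(config$n_lncrna)),
              miRNA = sprintf("MIR%04d", seq_len(config$n_mirna)))

  nt <- config$n_triplets
  nde <- config$n_de_per_class
  # planted DE genes: first nde ids per class; triplet members: first nt
  de_dir <- list()
  for (cl in names(ids)) {
    dirs <- character(nde)
    if (nde > 0) {
      if (cl != "miRNA" && nt > 0)
        dirs[seq_len(nt)] <- sample(c("up", "down"), nt, replace = TRUE)
      if (nde > nt)
        dirs[(nt + 1):nde] <- sample(c("up", "down"), nde - nt, replace = TRUE)
    }
    de_dir[[cl]] <- dirs
  }
  if (nt > 0) {
    # lncRNA shares the mRNA's direction; miRNA is anti-regulated
    de_dir$lncRNA[seq_len(nt)] <- de_dir$mRNA[seq_len(nt)]
    de_dir$miRNA[seq_len(nt)] <- ifelse(de_dir$mRNA[seq_len(nt)] == "up",
                                        "down", "up")
  }

  z <- if (nt > 0) matrix(stats::rnorm(nt * n), nt, n) else NULL

  simulate_class <- function(cl, loading_sign) {
    ng <- length(ids[[cl]])
    base <- stats::rnorm(ng, mean = 8, sd = 1)
    m <- matrix(stats::rnorm(ng * n, sd = config$noise_sd), ng, n)
    m <- m + base
    if (nde > 0) {
      shift <- ifelse(de_dir[[cl]] == "up", 1, -1) * config$de_effect
      m[seq_len(nde), ] <- m[seq_len(nde), , drop = FALSE] +
        outer(shift, gsign)
    }
    if (nt > 0)
      m[seq_len(nt), ] <- m[seq_len(nt), , drop = FALSE] +
        loading_sign * config$coupling * z
    dimnames(m) <- list(ids[[cl]], samples)
    expr_matrix(m, cl)
  }
  mrna <- simulate_class("mRNA", +1)
  lncrna <- simulate_class("lncRNA", +1)
  mirna <- simulate_class("miRNA", -1)

  triplets <- if (nt > 0)
    data.frame(lncrna_id = ids$lncRNA[seq_len(nt)],
               mrna_id = ids$mRNA[seq_len(nt)],
               mirna_id = ids$miRNA[seq_len(nt)],
               stringsAsFactors = FALSE)
  else
    data.frame(lncrna_id = character(), mrna_id = character(),
               mirna_id = character(), stringsAsFactors = FALSE)

  func <- if (nt > 0)
    data.frame(
      mirna_id = rep(triplets$mirna_id, 2L),
      target_id = c(triplets$mrna_id, triplets$lncrna_id),
      target_class = rep(c("mRNA", "lncRNA"), each = nt),
      stringsAsFactors = FALSE)
  else
    data.frame(mirna_id = character(), target_id = character(),
               target_class = character(), stringsAsFactors = FALSE)

  # decoys: uniform over non-planted (miRNA, target) pairs, no replacement
  all_targets <- c(ids$mRNA, ids$lncRNA)
  target_cls <- rep(c("mRNA", "lncRNA"), c(config$n_mrna, config$n_lncrna))
  n_space <- config$n_mirna * length(all_targets)
  planted_key <- paste(func$mirna_id, func$target_id)
  n_decoy <- min(config$n_decoy_interactions, n_space - nrow(func))
  decoys <- data.frame(mirna_id = character(), target_id = character(),
                       target_class = character(), stringsAsFactors = FALSE)
  if (n_decoy > 0) {
    picked <- character(0)
    cells <- integer(0)
    while (length(cells) < n_decoy) {
      cand <- sample.int(n_space, n_decoy - length(cells), replace = FALSE)
      mi <- ((cand - 1L) %% config$n_mirna) + 1L
      tg <- ((cand - 1L) %/% config$n_mirna) + 1L
      key <- paste(ids$miRNA[mi], all_targets[tg])
      keep <- !(key %in% planted_key) & !(key %in% picked) & !duplicated(key)
      picked <- c(picked, key[keep])
      cells <- c(cells, cand[keep])
    }
    mi <- ((cells - 1L) %% config$n_mirna) + 1L
    tg <- ((cells - 1L) %/% config$n_mirna) + 1L
    decoys <- data.frame(mirna_id = ids$miRNA[mi],
                         target_id = all_targets[tg],
                         target_class = target_cls[tg],
                         stringsAsFactors = FALSE)
  }
  inter <- rbind(func, decoys)
  inter <- interaction_table(inter$mirna_id, inter$target_id,
                             inter$target_class)

  de_genes <- if (nde > 0)
    do.call(rbind, lapply(names(ids), function(cl)
      data.frame(gene_id = ids[[cl]][seq_len(nde)], rna_class = cl,
                 direction = de_dir[[cl]], stringsAsFactors = FALSE)))
  else
    data.frame(gene_id = character(), rna_class = character(),
               direction = character(), stringsAsFactors = FALSE)
  rownames(de_genes) <- NULL

  structure(list(
    mrna = mrna, lncrna = lncrna, mirna = mirna,
    labels = labels, interactions = inter,
    truth = list(de_genes = de_genes, triplets = triplets,
                 functional_interactions = interaction_table(
                   func$mirna_id, func$target_id, func$target_class)),
    config = config), class = "synthetic_dataset")
}

#' Write a synthetic dataset to a directory
#'
#' Emits the three expression matrices, the phenotype table, the interaction
#' table and a ground-truth sidecar, all tab-delimited; the matrices and
#' tables round-trip through the package readers.
#'
#' @param dataset a `synthetic_dataset` from [generate_dataset()].
#' @param directory destination directory (created if absent).
#' @return invisibly, the named vector of written file paths.
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(directory, f)
  write_expression_matrix(dataset$mrna, p("mrna.tsv"))
  write_expression_matrix(dataset$lncrna, p("lncrna.tsv"))
  write_expression_matrix(dataset$mirna, p("mirna.tsv"))
  write_group_labels(dataset$labels, p("phenotype.tsv"))
  write_interaction_table(dataset$interactions, p("interactions.tsv"))
  # ground-truth sidecar: versioned header comment, then sections
  con <- file(p("ground_truth.tsv"), "w")
  on.exit(close(con))
  writeLines("# cernet ground truth v1", con)
  tr <- dataset$truth$triplets
  de <- dataset$truth$de_genes
  writeLines("section\tfield1\tfield2\tfield3", con)
  if (nrow(de))
    writeLines(paste("de_gene", de$gene_id, de$rna_class, de$direction,
                     sep = "\t"), con)
  if (nrow(tr))
    writeLines(paste("triplet", tr$lncrna_id, tr$mrna_id, tr$mirna_id,
                     sep = "\t"), con)
  invisible(c(mrna = p("mrna.tsv"), lncrna = p("lncrna.tsv"),
              mirna = p("mirna.tsv"), phenotype = p("phenotype.tsv"),
              interactions = p("interactions.tsv"),
              ground_truth = p("ground_truth.tsv")))
}

#' @rdname write_dataset
#' @param path a ground-truth sidecar written by [write_dataset()].
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  de <- df[df$section == "de_gene", , drop = FALSE]
  tr <- df[df$section == "triplet", , drop = FALSE]
  list(de_genes = data.frame(gene_id = de$field1, rna_class = de$field2,
                             direction = de$field3, stringsAsFactors = FALSE),
       triplets = data.frame(lncrna_id = tr$field1, mrna_id = tr$field2,
                             mirna_id = tr$field3, stringsAsFactors = FALSE))
}
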