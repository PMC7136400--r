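#' Pipeline configuration
#'
#' Collects input paths, thresholds and seeds for [run_pipeline()].
#' Threshold defaults match the published procedure: raw p < 0.05 for
#' differential expression, lncRNA-mRNA PCC > 0.5 for candidate crosstalk,
#' negative (r < 0) miRNA co-expression for mediation.
#'
#' @param mrna,lncrna,mirna paths to the three expression matrices.
#' @param phenotype path to the two-column phenotype table.
#' @param interactions path to the miRNA-target interaction table.
#' @param gmt optional GMT gene-set file enabling the enrichment stage.
#' @param probe_map optional probe-to-gene map applied to the mRNA matrix.
#' @param de_alpha,pcc_threshold,neg_threshold stage thresholds.
#' @param rf an [rf_config()].
#' @param roc_threshold classification threshold on the vote fraction.
#' @param ci_method,ci_level AUC confidence-interval settings.
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mrna, lncrna, mirna, phenotype, interactions,
                            gmt = NULL, probe_map = NULL,
                            de_alpha = 0.05, pcc_threshold = 0.5,
                            neg_threshold = 0, rf = rf_config(),
                            roc_threshold = 0.5,
                            ci_method = "bootstrap", ci_level = 0.95,
                            seed = 1L, out_dir = "cernet_out") {
  paths <- c(mrna = mrna, lncrna = lncrna, mirna = mirna,
             phenotype = phenotype, interactions = interactions)
  if (!is.null(gmt)) paths <- c(paths, gmt = gmt)
  if (!is.null(probe_map)) paths <- c(paths, probe_map = probe_map)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  if (de_alpha <= 0 || de_alpha > 1) stop("`de_alpha` must be in (0, 1]")
  if (abs(pcc_threshold) > 1) stop("`pcc_threshold` must be in [-1, 1]")
  if (abs(neg_threshold) > 1) stop("`neg_threshold` must be in [-1, 1]")
  structure(list(paths = as.list(paths), de_alpha = de_alpha,
                 pcc_threshold = pcc_threshold,
                 neg_threshold = neg_threshold, rf = rf,
                 roc_threshold = roc_threshold, ci_method = ci_method,
                 ci_level = ci_level, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full ceRNA biomarker pipeline
#'
#' Executes differential expression on the three RNA classes, builds the
#' dysregulated ceRNA network, selects a lncRNA biomarker panel from the
#' network lncRNAs by random-forest OOB minimization, evaluates it by
#' LOOCV with ROC/AUC, and (when a GMT file is configured) runs
#' over-representation of the network mRNAs with term clustering. All
#' stage outputs are written under `out_dir`; the returned manifest echoes
#' the configuration and the per-stage counts.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return a `run_manifest` list (invisible copy also written as
#'   `manifest.json` in `out_dir`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)

  say("reading inputs")
  mats <- stage("read", {
    m <- read_expression_matrix(config$paths$mrna, "mRNA")
    if (!is.null(config$paths$probe_map))
      m <- collapse_probes(m, read_probe_map(config$paths$probe_map))
    list(mRNA = m,
         lncRNA = read_expression_matrix(config$paths$lncrna, "lncRNA"),
         miRNA = read_expression_matrix(config$paths$mirna, "miRNA"))
  })
  labels <- stage("read", read_group_labels(config$paths$phenotype))
  inter <- stage("read", read_interaction_table(config$paths$interactions))

  say("differential expression")
  de <- stage("diffexpr", lapply(mats, moderated_t_test, labels = labels))
  de_sets <- lapply(de, filter_de, alpha = config$de_alpha)
  for (cl in names(de))
    write_tsv(de[[cl]], p(sprintf("de_%s.tsv", tolower(cl))))
  de_counts <- lapply(de_sets, function(d)
    list(n = nrow(d), up = sum(d$direction == "up"),
         down = sum(d$direction == "down")))

  say("ceRNA network")
  net <- stage("cerna_network", {
    corr_lm <- pairwise_pcc(mats$lncRNA, mats$mRNA,
                            de_sets$lncRNA$gene_id, de_sets$mRNA$gene_id)
    cand <- candidate_pairs(corr_lm, config$pcc_threshold)
    trip <- if (nrow(cand) > 0 && nrow(de_sets$miRNA) > 0) {
      corr_im <- pairwise_pcc(mats$miRNA, mats$mRNA,
                              de_sets$miRNA$gene_id, de_sets$mRNA$gene_id)
      corr_il <- pairwise_pcc(mats$miRNA, mats$lncRNA,
                              de_sets$miRNA$gene_id, de_sets$lncRNA$gene_id)
      mediation_filter(cand, inter, corr_im, corr_il,
                       de_sets$miRNA$gene_id, config$neg_threshold)
    } else {
      data.frame(lncrna_id = character(), mrna_id = character(),
                 mirna_id = character(), r_lm = numeric(),
                 r_im = numeric(), r_il = numeric(),
                 stringsAsFactors = FALSE)
    }
    attr(trip, "n_candidates") <- nrow(cand)
    build_network(trip, provenance = list(
      pcc_threshold = config$pcc_threshold,
      neg_threshold = config$neg_threshold,
      de_alpha = config$de_alpha))
  })
  write_network(net, p("network.sif"), "sif")
  write_network(net, p("network_edges.tsv"), "edge_list")
  netsum <- network_summary(net)

  panel <- NULL; evaluation <- NULL
  net_lnc <- unique(net$triplets$lncrna_id)
  if (length(net_lnc) == 0) {
    warning("empty ceRNA network: no lncRNA candidates, skipping selection")
  } else {
    say("biomarker selection (", length(net_lnc), " candidate lncRNAs)")
    rf <- config$rf; rf$seed <- config$seed
    panel <- stage("biomarker_selection",
                   select_biomarkers(mats$lncRNA, labels,
                                     candidates = net_lnc, config = rf))
    write_panel(panel, p("panel.tsv"))
    say("LOOCV evaluation")
    preds <- stage("evaluation",
                   loocv_evaluate(mats$lncRNA, labels, panel, config = rf))
    roc <- roc_and_auc(preds)
    cm <- confusion_metrics(preds, threshold = config$roc_threshold)
    ci <- auc_ci(preds, level = config$ci_level,
                 method = config$ci_method, seed = config$seed)
    write_tsv(preds, p("loocv_predictions.tsv"))
    write_tsv(roc$roc, p("roc_points.tsv"))
    evaluation <- list(auc = roc$auc, auc_ci = c(ci$lower, ci$upper),
                       ci_method = ci$method,
                       accuracy = cm$accuracy, sensitivity = cm$sensitivity,
                       specificity = cm$specificity,
                       confusion = cm[c("tp", "fp", "tn", "fn")])
  }

  enr <- NULL
  if (!is.null(config$paths$gmt) && netsum$n_mrna > 0) {
    say("enrichment")
    enr <- stage("enrichment", {
      coll <- read_gmt(config$paths$gmt)
      ora <- hypergeom_ora(unique(net$triplets$mrna_id), coll)
      write_tsv(ora, p("enrichment.tsv"))
      hits <- ora[ora$enriched, , drop = FALSE]
      clusters <- if (nrow(hits) > 0) {
        tg <- term_overlap_graph(hits, coll)
        write_tsv(tg$edges, p("term_graph_edges.tsv"))
        length(unique(tg$clusters))
      } else 0L
      list(n_terms = nrow(ora), n_enriched = sum(ora$enriched),
           n_clusters = clusters)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cernet")),
    seed = config$seed,
    thresholds = list(de_alpha = config$de_alpha,
                      pcc_threshold = config$pcc_threshold,
                      neg_threshold = config$neg_threshold),
    input_digests = lapply(config$paths, function(f)
      unname(tools::md5sum(f))),
    n_samples = length(labels),
    de = de_counts,
    n_candidate_pairs = attr(net$triplets, "n_candidates"),
    network = netsum[c("n_nodes", "n_edges", "n_mirna", "n_mrna",
                       "n_lncrna", "n_triplets")],
    network_lncrna_fraction =
      if (de_counts$lncRNA$n > 0) netsum$n_lncrna / de_counts$lncRNA$n
      else NA_real_,
    panel = if (!is.null(panel)) list(
      size = length(panel$selected), features = panel$selected,
      oob_error = min(panel$oob_trace$oob_error)) else NULL,
    evaluation = evaluation,
    enrichment = enr)
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest), p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_panel <- function(panel, path) {
  imp <- panel$importance[panel$selected]
  write_tsv(data.frame(rank = seq_along(panel$selected),
                       id = panel$selected,
                       importance = format_num(unname(imp))), path)
}

#' Generate and analyze a small demonstration dataset
#'
#' Simulates a synthetic dataset, writes it to `dir/input`, runs the full
#' pipeline into `dir/output`, and returns the manifest. Used by the
#' documentation and smoke tests.
#'
#' @param seed integer seed driving both simulation and analysis.
#' @param dir destination directory (default a tempdir subdirectory).
#' @param config optional [synth_config()] override (its seed is replaced
#'   by `seed`).
#' @return the [run_pipeline()] manifest, invisibly; the directory path in
#'   attribute `"dir"`.
#' @export
make_demo <- function(seed = 1L, dir = file.path(tempdir(), "cernet_demo"),
                      config = NULL) {
  if (is.null(config)) config <- synth_config(seed = seed)
  else config$seed <- as.integer(seed)
  ds <- generate_dataset(config)
  files <- write_dataset(ds, file.path(dir, "input"))
  pc <- pipeline_config(
    mrna = files[["mrna"]], lncrna = files[["lncrna"]],
    mirna = files[["mirna"]], phenotype = files[["phenotype"]],
    interactions = files[["interactions"]],
    rf = rf_config(n_trees = 500, n_repeats = 3, seed = seed),
    seed = seed, out_dir = file.path(dir, "output"))
  manifest <- run_pipeline(pc, quiet = TRUE)
  attr(manifest, "dir") <- dir
  invisible(manifest)
}
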