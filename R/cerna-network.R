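#' Pairwise Pearson correlation between two gene sets
#'
#' Computes the Pearson correlation coefficient (PCC) for every requested
#' cross pair over the shared, identically ordered samples of two matrices.
#' Pairs involving a constant expression vector get `defined = FALSE` and
#' `r = NA` rather than propagating NaN.
#'
#' @param mat_a,mat_b [expr_matrix()] objects with identical sample order.
#' @param genes_a,genes_b gene ids to correlate (defaults: all rows).
#' @return data.frame `id_a`, `id_b`, `r`, `n`, `defined`.
#' @export
pairwise_pcc <- function(mat_a, mat_b,
                         genes_a = rownames(mat_a),
                         genes_b = rownames(mat_b)) {
  if (!identical(colnames(mat_a), colnames(mat_b)))
    stop("matrices must share identically ordered samples")
  n <- ncol(mat_a)
  if (n < 3) stop("correlation needs >= 3 samples")
  miss <- c(setdiff(genes_a, rownames(mat_a)),
            setdiff(genes_b, rownames(mat_b)))
  if (length(miss))
    stop("requested gene(s) not present: ", paste(miss, collapse = ", "))
  if (length(genes_a) == 0 || length(genes_b) == 0)
    return(data.frame(id_a = character(), id_b = character(), r = numeric(),
                      n = integer(), defined = logical(),
                      stringsAsFactors = FALSE))
  xa <- t(unclass(mat_a)[genes_a, , drop = FALSE])
  xb <- t(unclass(mat_b)[genes_b, , drop = FALSE])
  const_a <- apply(xa, 2, function(v) stats::sd(v) == 0)
  const_b <- apply(xb, 2, function(v) stats::sd(v) == 0)
  r <- suppressWarnings(stats::cor(xa, xb))
  out <- data.frame(
    id_a = rep(genes_a, times = length(genes_b)),
    id_b = rep(genes_b, each = length(genes_a)),
    r = as.vector(r), n = n,
    defined = !(rep(const_a, times = length(genes_b)) |
                  rep(const_b, each = length(genes_a))),
    stringsAsFactors = FALSE)
  out$r[!out$defined] <- NA_real_
  out
}

#' Candidate co-dysregulated lncRNA-mRNA pairs
#'
#' Retains pairs with `r > pcc_threshold` (strict; default 0.5), the first
#' stage of the ceRNA-network construction. Undefined correlations are
#' never retained.
#'
#' @param corr correlation table from [pairwise_pcc()] over
#'   DE lncRNAs x DE mRNAs (`id_a` = lncRNA, `id_b` = mRNA).
#' @param pcc_threshold strict lower bound on r.
#' @return data.frame `lncrna_id`, `mrna_id`, `r_lm`.
#' @export
candidate_pairs <- function(corr, pcc_threshold = 0.5) {
  keep <- corr$defined & !is.na(corr$r) & corr$r > pcc_threshold
  out <- data.frame(lncrna_id = corr$id_a[keep], mrna_id = corr$id_b[keep],
                    r_lm = corr$r[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Shared-miRNA mediation filter for candidate ceRNA pairs
#'
#' A candidate lncRNA-mRNA pair becomes a miRNA-mediated ceRNA triplet for
#' every differentially expressed miRNA that (a) targets both the mRNA and
#' the lncRNA according to the validated interaction table and (b) is
#' negatively co-expressed with both (`r < neg_threshold`, strict, default
#' 0). A pair with k qualifying miRNAs yields k triplets.
#'
#' @param candidates output of [candidate_pairs()].
#' @param interactions an [interaction_table()].
#' @param corr_im [pairwise_pcc()] table, miRNA (`id_a`) x mRNA (`id_b`).
#' @param corr_il [pairwise_pcc()] table, miRNA (`id_a`) x lncRNA (`id_b`).
#' @param de_mirnas ids of differentially expressed miRNAs.
#' @param neg_threshold strict upper bound on both miRNA correlations.
#' @return data.frame of triplets: `lncrna_id`, `mrna_id`, `mirna_id`,
#'   `r_lm`, `r_im`, `r_il`.
#' @export
mediation_filter <- function(candidates, interactions, corr_im, corr_il,
                             de_mirnas, neg_threshold = 0) {
  empty <- data.frame(lncrna_id = character(), mrna_id = character(),
                      mirna_id = character(), r_lm = numeric(),
                      r_im = numeric(), r_il = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(candidates) == 0 || length(de_mirnas) == 0) return(empty)
  tab <- as.data.frame(interactions)
  tab <- tab[tab$mirna_id %in% de_mirnas, , drop = FALSE]
  targets_m <- split(tab$target_id[tab$target_class == "mRNA"],
                     tab$mirna_id[tab$target_class == "mRNA"])
  targets_l <- split(tab$target_id[tab$target_class == "lncRNA"],
                     tab$mirna_id[tab$target_class == "lncRNA"])
  pair_key <- function(a, b) {
    if (length(a) == 0) character(0) else paste0(a, "\r", b)
  }
  key_im <- stats::setNames(corr_im$r, pair_key(corr_im$id_a, corr_im$id_b))
  key_il <- stats::setNames(corr_il$r, pair_key(corr_il$id_a, corr_il$id_b))
  def_im <- stats::setNames(corr_im$defined,
                            pair_key(corr_im$id_a, corr_im$id_b))
  def_il <- stats::setNames(corr_il$defined,
                            pair_key(corr_il$id_a, corr_il$id_b))

  rows <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    l <- candidates$lncrna_id[i]
    m <- candidates$mrna_id[i]
    shared <- intersect(names(targets_m)[vapply(targets_m, function(t)
      m %in% t, logical(1))],
      names(targets_l)[vapply(targets_l, function(t) l %in% t, logical(1))])
    if (length(shared) == 0) next
    km <- paste0(shared, "\r", m)
    kl <- paste0(shared, "\r", l)
    missing <- c(km[!(km %in% names(key_im))], kl[!(kl %in% names(key_il))])
    if (length(missing))
      stop("missing correlation entr", if (length(missing) > 1) "ies" else "y",
           " for required miRNA pair(s): ",
           paste(gsub("\r", " ~ ", missing), collapse = ", "))
    r_im <- key_im[km]; r_il <- key_il[kl]
    ok <- def_im[km] & def_il[kl] &
      !is.na(r_im) & !is.na(r_il) &
      r_im < neg_threshold & r_il < neg_threshold
    if (!any(ok)) next
    rows[[i]] <- data.frame(
      lncrna_id = l, mrna_id = m, mirna_id = shared[ok],
      r_lm = candidates$r_lm[i], r_im = unname(r_im[ok]),
      r_il = unname(r_il[ok]), stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$lncrna_id, out$mrna_id, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the dysregulated ceRNA network from accepted triplets
#'
#' Integrates the triplet set into one typed graph: nodes carry their RNA
#' class; edges are of kind `lnc_m_cerna` (the lncRNA-mRNA crosstalk),
#' `mi_m_target` and `mi_l_target` (the mediating miRNA's targeting
#' relations); node and edge sets are deduplicated and ordered
#' deterministically.
#'
#' @param triplets output of [mediation_filter()].
#' @param provenance optional named list (thresholds etc.) stored verbatim.
#' @return a `cerna_network`: list with `nodes` (data.frame `id`,
#'   `rna_class`), `edges` (data.frame `from`, `to`, `kind`), `triplets`,
#'   `provenance`.
#' @export
build_network <- function(triplets, provenance = list()) {
  if (nrow(triplets) == 0) {
    nodes <- data.frame(id = character(), rna_class = character(),
                        stringsAsFactors = FALSE)
    edges <- data.frame(from = character(), to = character(),
                        kind = character(), stringsAsFactors = FALSE)
  } else {
    nodes <- unique(rbind(
      data.frame(id = triplets$lncrna_id, rna_class = "lncRNA",
                 stringsAsFactors = FALSE),
      data.frame(id = triplets$mrna_id, rna_class = "mRNA",
                 stringsAsFactors = FALSE),
      data.frame(id = triplets$mirna_id, rna_class = "miRNA",
                 stringsAsFactors = FALSE)))
    nodes <- nodes[order(nodes$rna_class, nodes$id), , drop = FALSE]
    edges <- unique(rbind(
      data.frame(from = triplets$lncrna_id, to = triplets$mrna_id,
                 kind = "lnc_m_cerna", stringsAsFactors = FALSE),
      data.frame(from = triplets$mirna_id, to = triplets$mrna_id,
                 kind = "mi_m_target", stringsAsFactors = FALSE),
      data.frame(from = triplets$mirna_id, to = triplets$lncrna_id,
                 kind = "mi_l_target", stringsAsFactors = FALSE)))
    edges <- edges[order(edges$kind, edges$from, edges$to), , drop = FALSE]
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, triplets = triplets,
                 provenance = provenance), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "cerna_network: %d nodes (%d miRNA, %d mRNA, %d lncRNA), %d edges, %d triplets\n",
    s$n_nodes, s$n_mirna, s$n_mrna, s$n_lncrna, s$n_edges, s$n_triplets))
  invisible(x)
}

#' Summary counts of a ceRNA network
#'
#' @param network a `cerna_network`.
#' @return list with `n_nodes`, `n_edges`, per-class node counts
#'   (`n_mirna`, `n_mrna`, `n_lncrna`), per-kind edge counts, `n_triplets`
#'   and the node `degree` table.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  cls <- table(factor(network$nodes$rna_class,
                      levels = c("miRNA", "mRNA", "lncRNA")))
  knd <- table(factor(network$edges$kind,
                      levels = c("lnc_m_cerna", "mi_m_target", "mi_l_target")))
  deg <- table(factor(c(network$edges$from, network$edges$to),
                      levels = network$nodes$id))
  list(n_nodes = nrow(network$nodes), n_edges = nrow(network$edges),
       n_mirna = unname(cls[["miRNA"]]), n_mrna = unname(cls[["mRNA"]]),
       n_lncrna = unname(cls[["lncRNA"]]),
       edge_kinds = stats::setNames(as.integer(knd), names(knd)),
       n_triplets = nrow(network$triplets),
       degree = stats::setNames(as.integer(deg), names(deg)))
}

#' Node-count arithmetic for a network summary
#'
#' Total node count implied by per-class counts; used for manifest
#' consistency checks.
#'
#' @param n_mirna,n_mrna,n_lncrna per-class node counts.
#' @return their sum.
#' @export
node_total <- function(n_mirna, n_mrna, n_lncrna) {
  stopifnot(n_mirna >= 0, n_mrna >= 0, n_lncrna >= 0)
  n_mirna + n_mrna + n_lncrna
}

network_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = network$nodes)
}

#' Write a ceRNA network to disk
#'
#' `sif` writes Cytoscape simple-interaction lines using the edge kind as
#' the relation token; `graphml` carries node `rna_class` and edge `kind`
#' attributes; `edge_list` is tab-delimited with a header and round-trips
#' through [read_edge_list()].
#'
#' @param network a `cerna_network`.
#' @param path destination file.
#' @param format one of `"sif"`, `"graphml"`, `"edge_list"`.
#' @export
write_network <- function(network, path,
                          format = c("sif", "graphml", "edge_list")) {
  format <- match.arg(format)
  if (format == "sif") {
    writeLines(paste(network$edges$from, network$edges$kind,
                     network$edges$to, sep = "\t"), path)
  } else if (format == "graphml") {
    if (nrow(network$nodes) == 0) {
      g <- igraph::make_empty_graph(0, directed = FALSE)
    } else {
      g <- network_igraph(network)
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_tsv(network$edges, path)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("from", "to", "kind")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  df[, need]
}
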