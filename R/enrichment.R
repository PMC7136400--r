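#' Hypergeometric over-representation analysis
#'
#' Tests each gene set in the collection for over-representation of the
#' query genes within the declared universe. The p-value is the upper tail
#' \eqn{P[X \ge k]} of the hypergeometric distribution with `k` the
#' query/set overlap, `K` the set size, `n` the query size and `N` the
#' universe size; BH q-values are reported alongside and rows with
#' `p < alpha` are flagged enriched.
#'
#' @param query character vector of gene ids.
#' @param collection a [gene_set_collection()].
#' @param alpha raw-p enrichment flag cutoff (default 0.05).
#' @return data.frame `term`, `k`, `K`, `n`, `N`, `p_value`, `q_value`,
#'   `enriched`, ordered by `p_value` then term.
#' @export
hypergeom_ora <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  q <- intersect(unique(query), collection$universe)
  if (length(q) == 0)
    stop("query has no genes in the universe")
  N <- length(collection$universe)
  n <- length(q)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    k <- length(intersect(q, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- out$p_value < alpha
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment-map style term overlap graph
#'
#' Connects enriched terms whose member gene sets overlap at or above a
#' cutoff, and labels connected components as term clusters — the
#' computation behind an enrichment map, without the rendering.
#'
#' @param enriched rows of [hypergeom_ora()] output to use as nodes
#'   (typically the `enriched` subset).
#' @param collection the [gene_set_collection()] the terms came from.
#' @param metric `"jaccard"` (|A∩B| / |A∪B|, default) or
#'   `"overlap_coefficient"` (|A∩B| / min(|A|, |B|)).
#' @param cutoff edge kept iff weight >= cutoff (default 0.25).
#' @return a `term_graph`: list with `nodes` (term ids, sorted), `edges`
#'   (data.frame `term_a`, `term_b`, `weight`), `clusters` (named integer
#'   vector of component labels), `metric`, `cutoff`.
#' @export
term_overlap_graph <- function(enriched, collection,
                               metric = c("jaccard", "overlap_coefficient"),
                               cutoff = 0.25) {
  metric <- match.arg(metric)
  stopifnot(inherits(collection, "gene_set_collection"))
  if (nrow(enriched) == 0) stop("enriched table is empty")
  terms <- sort(unique(enriched$term))
  miss <- setdiff(terms, names(collection$sets))
  if (length(miss))
    stop("term(s) not in collection: ", paste(miss, collapse = ", "))
  edges <- list()
  if (length(terms) > 1) {
    combs <- utils::combn(terms, 2)
    w <- apply(combs, 2, function(pr) {
      a <- collection$sets[[pr[1]]]; b <- collection$sets[[pr[2]]]
      ov <- length(intersect(a, b))
      if (metric == "jaccard") ov / length(union(a, b))
      else ov / min(length(a), length(b))
    })
    keep <- w >= cutoff
    edges <- data.frame(term_a = combs[1, keep], term_b = combs[2, keep],
                        weight = w[keep], stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(term_a = character(), term_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = terms)
  comp <- igraph::components(g)$membership
  structure(list(nodes = terms, edges = edges,
                 clusters = stats::setNames(as.integer(comp[terms]), terms),
                 metric = metric, cutoff = cutoff),
            class = "term_graph")
}

#' @export
print.term_graph <- function(x, ...) {
  cat(sprintf("term_graph: %d terms, %d edges (%s >= %g), %d cluster(s)\n",
              length(x$nodes), nrow(x$edges), x$metric, x$cutoff,
              length(unique(x$clusters))))
  invisible(x)
}
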