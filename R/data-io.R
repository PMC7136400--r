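#' Construct an expression matrix for one RNA class
#'
#' An `expr_matrix` is a numeric matrix of log2 expression values with genes
#' in rows and samples in columns, tagged with the RNA class it describes.
#' Gene and sample identifiers must be unique and every value finite.
#'
#' @param values numeric matrix, genes x samples, with row and column names.
#' @param rna_class one of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, rna_class = c("mRNA", "lncRNA", "miRNA")) {
  rna_class <- match.arg(rna_class)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite expression value at gene '", rownames(values)[bad[1]],
         "', sample '", colnames(values)[bad[2]], "'")
  }
  structure(values, rna_class = rna_class, class = c("expr_matrix", "matrix"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples\n",
              attr(x, "rna_class"), nrow(x), ncol(x)))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x object to query.
#' @export
rna_class <- function(x) attr(x, "rna_class")

#' Two-group sample labels
#'
#' Phenotype labels mapping sample ids to the two bone-mineral-density
#' groups used throughout the pipeline.
#'
#' @param sample_ids character vector of sample ids.
#' @param groups character vector, each element `"high_BMD"` or `"low_BMD"`.
#' @return a named factor with levels `high_BMD`, `low_BMD`.
#' @export
group_labels <- function(sample_ids, groups) {
  if (length(sample_ids) != length(groups))
    stop("sample_ids and groups differ in length")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s) in labels")
  bad <- setdiff(unique(groups), c("high_BMD", "low_BMD"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  out <- factor(groups, levels = c("high_BMD", "low_BMD"))
  if (any(table(out) == 0))
    stop("both groups must be non-empty")
  names(out) <- sample_ids
  out
}

check_labels <- function(mat, labels) {
  if (!setequal(colnames(mat), names(labels)) ||
      length(labels) != ncol(mat))
    stop("labels do not cover exactly the matrix samples")
  labels[colnames(mat)]
}

#' Validated miRNA-target interaction table
#'
#' @param mirna_id,target_id character vectors of equal length.
#' @param target_class character vector, `"mRNA"` or `"lncRNA"` per record.
#' @return a data.frame of class `interaction_table` with the three columns,
#'   duplicate records removed.
#' @export
interaction_table <- function(mirna_id, target_id, target_class) {
  bad <- setdiff(unique(target_class), c("mRNA", "lncRNA"))
  if (length(bad))
    stop("unknown target_class token(s): ", paste(bad, collapse = ", "))
  df <- data.frame(mirna_id = as.character(mirna_id),
                   target_id = as.character(target_id),
                   target_class = as.character(target_class),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids; first column holds gene ids.
#' Duplicated gene ids are an error, never merged silently.
#'
#' @param path file path.
#' @param rna_class RNA class tag for the matrix.
#' @return an [expr_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   rna_class = c("mRNA", "lncRNA", "miRNA")) {
  rna_class <- match.arg(rna_class)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed header in ", path,
                         ": need gene id column plus >= 1 sample column")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop("non-numeric cell in ", path, " at gene '", ids[bad],
           "', sample '", names(vals)[j], "'")
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  expr_matrix(m, rna_class)
}

#' Write an expression matrix to a tab-delimited file
#'
#' @param mat an [expr_matrix()].
#' @param path destination file.
#' @param id_column name for the gene id column in the header.
#' @export
write_expression_matrix <- function(mat, path, id_column = "gene_id") {
  df <- data.frame(rownames(mat), format_num(unclass(mat)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(mat))
  write_tsv(df, path)
}

# fixed-format numbers so identical data gives identical bytes on disk
format_num <- function(x) {
  out <- vapply(as.vector(x), function(v) sprintf("%.10g", v), character(1))
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed writing ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read a phenotype table of group labels
#'
#' Two tab-delimited columns: sample id and group (`high_BMD` / `low_BMD`).
#'
#' @param path file path.
#' @return named factor as from [group_labels()].
#' @export
read_group_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("phenotype table needs two columns in ", path)
  group_labels(as.character(df[[1]]), as.character(df[[2]]))
}

#' @rdname read_group_labels
#' @param labels a [group_labels()] factor.
#' @export
write_group_labels <- function(labels, path) {
  write_tsv(data.frame(sample_id = names(labels),
                       group = as.character(labels)), path)
}

#' Read a miRNA-target interaction table
#'
#' Three tab-delimited columns: miRNA id, target id, target class
#' (`mRNA` or `lncRNA`), in the style of TarBase exports. Duplicate rows
#' are collapsed; unknown class tokens are rejected.
#'
#' @param path file path.
#' @return an [interaction_table()].
#' @export
read_interaction_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("mirna_id", "target_id", "target_class")
  if (!all(need %in% names(df)))
    stop("missing column(s) in ", path, ": ",
         paste(setdiff(need, names(df)), collapse = ", "))
  interaction_table(df$mirna_id, df$target_id, df$target_class)
}

#' @rdname read_interaction_table
#' @param tab an [interaction_table()].
#' @export
write_interaction_table <- function(tab, path) {
  write_tsv(as.data.frame(tab), path)
}

#' Read a two-column probe-to-gene map
#'
#' @param path tab-delimited file with columns probe id, gene id.
#' @return named character vector, probe id -> gene id.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("probe map needs two columns in ", path)
  gene <- as.character(df[[2]])
  if (any(!nzchar(gene))) stop("empty gene id in probe map ", path)
  stats::setNames(gene, as.character(df[[1]]))
}

#' Collapse a probe-level matrix to gene level
#'
#' When several probes map to one gene, the probe with the highest variance
#' across samples is kept (ties broken by probe id order). Unmapped probes
#' are dropped and counted in a message.
#'
#' @param mat probe-level [expr_matrix()] (rownames are probe ids).
#' @param probe_map named character vector from [read_probe_map()].
#' @return gene-level [expr_matrix()].
#' @export
collapse_probes <- function(mat, probe_map) {
  present <- intersect(rownames(mat), names(probe_map))
  if (length(present) == 0)
    stop("probe map covers none of the matrix probes")
  dropped <- nrow(mat) - length(present)
  if (dropped > 0)
    message(dropped, " unmapped probe(s) dropped")
  sub <- unclass(mat)[present, , drop = FALSE]
  gene <- probe_map[present]
  v <- apply(sub, 1, stats::var)
  ord <- order(gene, -v, present)          # per gene: highest variance first
  keep <- ord[!duplicated(gene[ord])]
  out <- sub[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  out <- out[order(rownames(out)), , drop = FALSE]
  expr_matrix(out, rna_class(mat))
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-delimited fields
#' `name`, `description`, then member gene ids.
#'
#' @param path GMT file path.
#' @param universe background gene id set; defaults to the union of all sets.
#' @return a `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line (need name, description, >=1 member): ",
           substr(ln, 1, 40))
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  gene_set_collection(sets, universe)
}

#' @rdname read_gmt
#' @param sets named list of character vectors (each non-empty).
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (length(sets) == 0 || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("`sets` must be a non-empty named list")
  if (any(lengths(sets) == 0)) stop("every gene set must be non-empty")
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  if (any(lengths(sets) == 0))
    stop("a set became empty after restriction to the universe")
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}
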