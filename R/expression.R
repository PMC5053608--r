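#' Expression matrix with two-group phenotype labels
#'
#' Container for a genes x samples expression matrix together with a
#' two-level phenotype label per sample. All set-level tests in the package
#' compare the two phenotype groups; the first distinct label encountered is
#' taken as group 1.
#'
#' @param values Numeric matrix, one row per gene, one column per sample.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(values)`.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   column. Defaults to `colnames(values)`.
#' @param group_labels Phenotype label per sample; exactly two distinct
#'   labels must be present and each group must contain at least two samples.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `group_labels`, `groups` (the two
#'   labels, group 1 first).
#' @export
#' @examples
#' x <- matrix(rnorm(20), 4, 5)
#' expression_matrix(x, paste0("g", 1:4), paste0("s", 1:5),
#'                   c("A", "A", "A", "B", "B"))
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values), group_labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  group_labels <- as.character(group_labels)
  if (length(gene_ids) != nrow(values))
    stop("number of gene_ids must equal the row count")
  if (anyDuplicated(gene_ids))
    stop("gene_ids must be unique")
  if (length(sample_ids) != ncol(values))
    stop("number of sample_ids must equal the column count")
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  if (length(group_labels) != ncol(values))
    stop("one group label per sample required")
  groups <- unique(group_labels)
  if (length(groups) != 2L)
    stop("exactly two distinct group labels required, got ", length(groups))
  if (any(table(group_labels) < 2L))
    stop("each group must contain at least two samples")
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, group_labels = group_labels,
                 groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(factor(x$group_labels, levels = x$groups))
  cat(sprintf("expression_matrix: %d genes x %d samples (%s: %d, %s: %d)\n",
              nrow(x$values), ncol(x$values),
              x$groups[1], tab[1], x$groups[2], tab[2]))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# logical mask of group-1 samples
group1_mask <- function(mat) mat$group_labels == mat$groups[1]

group_sizes <- function(mat) {
  g1 <- group1_mask(mat)
  c(n1 = sum(g1), n2 = sum(!g1))
}

#' Read an expression matrix and phenotype labels from delimited files
#'
#' The expression file is TSV or CSV (extension- and content-sniffed) with
#' gene identifiers in the first column and a header row of sample
#' identifiers. The label file has two columns, sample id and group label,
#' with or without a header. Duplicate gene ids keep the first occurrence
#' with a warning; samples are matched to labels by id, and samples without
#' a label (or labels without a sample) are an error.
#'
#' @param path Path to the expression matrix file.
#' @param labels_path Path to the two-column sample label file.
#' @param sep Field separator; `NULL` (default) guesses tab for `.tsv`/`.txt`
#'   and comma for `.csv`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, labels_path, sep = NULL) {
  guess_sep <- function(p) {
    if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  }
  s <- if (is.null(sep)) guess_sep(path) else sep
  df <- utils::read.table(path, header = TRUE, sep = s, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(ids)) {
    warning("duplicate gene ids in ", path, "; keeping first occurrence")
    keep <- !duplicated(ids)
    ids <- ids[keep]
    vals <- vals[keep, , drop = FALSE]
  }
  s2 <- if (is.null(sep)) guess_sep(labels_path) else sep
  lab <- utils::read.table(labels_path, header = FALSE, sep = s2,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  # tolerate a header row ("sample...", "group...")
  if (nrow(lab) > 0 && !lab[1, 1] %in% colnames(vals)) lab <- lab[-1, , drop = FALSE]
  if (ncol(lab) < 2L) stop("label file must have two columns: sample id, group")
  lab_map <- stats::setNames(as.character(lab[[2L]]), as.character(lab[[1L]]))
  missing <- setdiff(colnames(vals), names(lab_map))
  if (length(missing))
    stop("no label for sample(s): ", paste(missing, collapse = ", "))
  expression_matrix(vals, ids, colnames(vals), lab_map[colnames(vals)])
}
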