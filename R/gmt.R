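#' Read a gene-set collection in GMT format
#'
#' One set per line, tab-separated: name, description, then gene ids (the
#' format MSigDB collections are distributed in). Lines with fewer than
#' three fields are an error naming the offending line; duplicate gene ids
#' within a line are removed with a warning; duplicate set names across
#' lines are an error.
#'
#' @param path Path to a `.gmt` file.
#' @return An object of class `gene_set_collection`: a list with `sets`
#'   (list of [gene_set()]) and `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes))
      warning("duplicate gene ids in set '", fields[1L], "' (line ", i,
              "); deduplicated")
    sets[[i]] <- gene_set(fields[1L], unique(genes), fields[2L])
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  structure(list(sets = sets, source = path), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets from %s\n",
              length(x$sets), x$source))
  invisible(x)
}

#' Restrict a gene-set collection to genes present in the data
#'
#' Drops, per set, gene ids absent from the expression matrix (matching is
#' exact and case-sensitive) and records the count of genes found. Sets
#' reduced below two genes are flagged `skipped` and excluded downstream,
#' with a warning.
#'
#' @param collection A `gene_set_collection`.
#' @param mat An [expression_matrix()].
#' @return A `gene_set_collection` whose sets carry extra elements
#'   `n_annotated` (original size), `genes_found`, and `skipped`.
#' @export
match_sets <- function(collection, mat) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(mat, "expression_matrix"))
  skipped <- character(0)
  sets <- lapply(collection$sets, function(s) {
    n_annot <- length(s$gene_ids)
    found <- intersect(s$gene_ids, mat$gene_ids)
    out <- s
    out$n_annotated <- n_annot
    out$genes_found <- length(found)
    out$skipped <- length(found) < 2L
    if (!out$skipped) out$gene_ids <- found
    out
  })
  skipped <- names(sets)[vapply(sets, `[[`, logical(1), "skipped")]
  if (length(skipped))
    warning("set(s) with fewer than 2 genes in the data skipped: ",
            paste(skipped, collapse = ", "))
  structure(list(sets = sets, source = collection$source),
            class = "gene_set_collection")
}
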