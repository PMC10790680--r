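# Plain-text I/O: expression TSV (first column gene_id, header = sample
# ids), labels TSV, weighted edge TSV, gene-list TXT, and PLS models as
# JSON.

#' @rdname plspair-io
#' @param expr genes x samples matrix.
#' @param path file path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read and write pipeline artifacts
#'
#' Tabular artifacts are TSV with a header row; gene lists are one symbol
#' per line; models are JSON.
#'
#' @name plspair-io
#' @rdname plspair-io
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname plspair-io
#' @param labels data.frame with `sample_id`, `response`.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels[c("sample_id", "response")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' @rdname plspair-io
#' @export
read_labels <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname plspair-io
#' @param edges data.frame with `node1`, `node2`, `combined_score`.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges[c("node1", "node2", "combined_score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname plspair-io
#' @export
read_edges <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname plspair-io
#' @param genes character vector of gene symbols.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
}

#' @rdname plspair-io
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname plspair-io
#' @param model a `pls_model`.
#' @export
write_pls_model <- function(model, path) {
  jsonlite::write_json(
    list(panel = model$panel,
         weights = as.list(model$weights),
         threshold = model$threshold,
         center = as.list(model$center),
         scale = as.list(model$scale),
         reference_gene = model$reference_gene,
         degenerate = model$degenerate),
    path, auto_unbox = TRUE, digits = NA)
}

#' @rdname plspair-io
#' @export
read_pls_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(panel = j$panel,
                 weights = unlist(j$weights),
                 threshold = j$threshold,
                 center = unlist(j$center),
                 scale = unlist(j$scale),
                 reference_gene = j$reference_gene,
                 degenerate = isTRUE(j$degenerate)),
            class = "pls_model")
}
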