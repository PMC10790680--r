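# Differential expression between responders and nonresponders:
# unpaired pooled-variance (Student) t-test per gene on log2-scale input,
# with a p-value / |log2 fold-change| filter.

match_labels <- function(expr, labels) {
  stopifnot(is.matrix(expr), is.data.frame(labels),
            all(c("sample_id", "response") %in% names(labels)))
  idx <- match(colnames(expr), labels$sample_id)
  if (anyNA(idx))
    stop("samples missing from labels: ",
         paste(colnames(expr)[is.na(idx)], collapse = ", "), call. = FALSE)
  resp <- labels$response[idx]
  bad <- setdiff(unique(resp), c("responder", "nonresponder"))
  if (length(bad))
    stop("unknown response labels: ", paste(bad, collapse = ", "), call. = FALSE)
  resp
}

#' Per-gene two-class differential expression test
#'
#' Two-sided unpaired Student t-test (pooled variance) per gene, with
#' log2 fold-change defined as mean(responders) - mean(nonresponders);
#' input is assumed to be on the log2 scale. Genes that are constant
#' within both groups get t = 0 and p = 1 when the group means agree
#' (and p = 0 when they differ), by convention.
#'
#' @param expr genes x samples numeric matrix (log2 scale), rownames =
#'   gene ids, colnames = sample ids.
#' @param labels data.frame with `sample_id` and `response`
#'   (`"responder"` / `"nonresponder"`).
#' @param gene_class optional single string or per-gene vector recorded in
#'   the output (`"lncRNA"` / `"mRNA"`).
#' @return data.frame: `gene_id`, `gene_class`, `log2_fc`, `t`, `p`,
#'   `direction` (`"up"` iff `log2_fc > 0`).
#' @export
de_test <- function(expr, labels, gene_class = NA_character_) {
  resp <- match_labels(expr, labels)
  i1 <- resp == "responder"; i2 <- !i1
  if (sum(i1) < 2L || sum(i2) < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  if (!all(is.finite(expr)))
    stop("expression matrix contains non-finite values", call. = FALSE)

  one <- function(x) {
    x1 <- x[i1]; x2 <- x[i2]
    if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
      fc <- mean(x1) - mean(x2)
      if (fc == 0) return(c(fc, 0, 1))
      return(c(fc, sign(fc) * Inf, 0))
    }
    ht <- stats::t.test(x1, x2, var.equal = TRUE)
    c(mean(x1) - mean(x2), unname(ht$statistic), ht$p.value)
  }
  res <- t(apply(expr, 1L, one))
  data.frame(gene_id = rownames(expr),
             gene_class = gene_class,
             log2_fc = res[, 1], t = res[, 2], p = res[, 3],
             direction = ifelse(res[, 1] > 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter a differential-expression table
#'
#' Keeps genes with `p < p_threshold` and `|log2_fc| >= lfc_threshold`.
#' No multiple-testing correction is applied by default (the screen uses
#' raw p-values); `adjust = "BH"` filters on Benjamini-Hochberg adjusted
#' p-values instead.
#'
#' @param de output of [de_test()].
#' @param p_threshold raw (or adjusted) p-value cutoff, in (0, 1].
#' @param lfc_threshold absolute log2 fold-change cutoff, >= 0.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return list: `table` (the surviving rows, original order),
#'   `n_up`, `n_down`.
#' @export
filter_de <- function(de, p_threshold = 0.05, lfc_threshold = 1,
                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1)
    stop("p_threshold must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(lfc_threshold) || lfc_threshold < 0)
    stop("lfc_threshold must be non-negative", call. = FALSE)
  p <- if (adjust == "BH") stats::p.adjust(de$p, "BH") else de$p
  keep <- !is.na(p) & p < p_threshold & abs(de$log2_fc) >= lfc_threshold
  tab <- de[keep, , drop = FALSE]
  list(table = tab,
       n_up = sum(tab$direction == "up"),
       n_down = sum(tab$direction == "down"))
}
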