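# lncRNA-mRNA co-expression screening: Pearson correlation of every
# lncRNA x mRNA pair separately within responders and nonresponders,
# retention of pairs significant in both groups, and intersection of the
# mRNA side with a drug-target list.

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with significance from the t-transform on n - 2
#' degrees of freedom (as in [stats::cor.test()]).
#'
#' @param x,y numeric vectors, length >= 3, finite, non-constant.
#' @return named numeric: `r`, `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  ht <- stats::cor.test(x, y)
  c(r = unname(ht$estimate), p = ht$p.value)
}

# vectorized p for a correlation matrix at n observations
cor_p_matrix <- function(R, n) {
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, 0))
  P <- 2 * stats::pt(-abs(tstat), df = n - 2)
  P[R^2 >= 1] <- 0
  P
}

#' Screen lncRNA-mRNA pairs correlated within both response groups
#'
#' Computes all lncRNA x mRNA Pearson correlations separately within
#' responders and within nonresponders and retains, per group, the pairs
#' with p below `p_threshold`; the `both` table is the intersection
#' significant in both groups, carrying each group's r and p and
#' `mean_abs_r = (|r_responder| + |r_nonresponder|) / 2`.
#'
#' Zero-variance genes within a group yield undefined correlations; such
#' pairs are dropped with a warning.
#'
#' @param expr_lnc,expr_mrna genes x samples matrices (typically restricted
#'   to differentially expressed genes).
#' @param labels data.frame with `sample_id`, `response`.
#' @param p_threshold per-group significance cutoff on raw (or BH-adjusted)
#'   p-values.
#' @param adjust `"none"` (default) or `"BH"` (within each group, across
#'   all pairs).
#' @return list of data.frames `responder`, `nonresponder` (columns
#'   `lnc_id`, `mrna_id`, `r`, `p`) and `both` (per-group r/p plus
#'   `mean_abs_r`), each sorted by (`lnc_id`, `mrna_id`).
#' @export
screen_pairs <- function(expr_lnc, expr_mrna, labels, p_threshold = 0.05,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (nrow(expr_lnc) < 1L || nrow(expr_mrna) < 1L)
    stop("empty expression matrix", call. = FALSE)
  resp <- match_labels(expr_lnc, labels)
  if (!identical(colnames(expr_lnc), colnames(expr_mrna)))
    stop("lncRNA and mRNA matrices must share sample columns", call. = FALSE)

  group_table <- function(keep) {
    n <- sum(keep)
    if (n < 3L) stop("need at least 3 samples per group", call. = FALSE)
    X <- t(expr_lnc[, keep, drop = FALSE])
    Y <- t(expr_mrna[, keep, drop = FALSE])
    R <- suppressWarnings(stats::cor(X, Y))
    P <- cor_p_matrix(R, n)
    df <- data.frame(lnc_id = rep(rownames(expr_lnc), times = ncol(R)),
                     mrna_id = rep(colnames(R), each = nrow(R)),
                     r = as.vector(R), p = as.vector(P),
                     stringsAsFactors = FALSE)
    if (anyNA(df$r)) {
      warning("dropping pairs with undefined (zero-variance) correlations")
      df <- df[!is.na(df$r), , drop = FALSE]
    }
    if (adjust == "BH") df$p <- stats::p.adjust(df$p, "BH")
    df
  }
  tab_r <- group_table(resp == "responder")
  tab_n <- group_table(resp == "nonresponder")

  sig_r <- tab_r[tab_r$p < p_threshold, , drop = FALSE]
  sig_n <- tab_n[tab_n$p < p_threshold, , drop = FALSE]
  both <- merge(sig_r, sig_n, by = c("lnc_id", "mrna_id"),
                suffixes = c("_responder", "_nonresponder"))
  both$mean_abs_r <- (abs(both$r_responder) + abs(both$r_nonresponder)) / 2

  ord <- function(d) d[order(d$lnc_id, d$mrna_id), , drop = FALSE]
  list(responder = ord(sig_r), nonresponder = ord(sig_n), both = ord(both))
}

#' Intersect candidate pairs with a drug-target gene list
#'
#' Retains pairs whose mRNA symbol is on the target list (exact,
#' case-sensitive match after whitespace stripping) and reports the
#' Venn counts behind the intersection.
#'
#' @param pairs data.frame of pairs with `lnc_id`, `mrna_id` columns
#'   (typically the `both` table of [screen_pairs()]).
#' @param targets character vector of target gene symbols.
#' @return list: `candidates` (retained pairs), `venn` (named counts:
#'   `pairs`, `targets`, `overlap` = distinct pair mRNAs on the list).
#' @export
intersect_targets <- function(pairs, targets) {
  targets <- trimws(as.character(targets))
  targets <- targets[nzchar(targets)]
  keep <- trimws(pairs$mrna_id) %in% targets
  candidates <- pairs[keep, , drop = FALSE]
  list(candidates = candidates,
       venn = c(pairs = nrow(pairs), targets = length(unique(targets)),
                overlap = length(unique(candidates$mrna_id))))
}
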