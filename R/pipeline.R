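# End-to-end orchestration: discovery (differential expression ->
# within-group co-expression -> drug-target intersection -> network
# ranking) and prediction (per-normalization PLS fit, cross-validation,
# and paired-vs-single-gene ROC comparison).

check_threshold <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x > 1)
    stop("invalid ", name, ": must lie in (0, 1]", call. = FALSE)
}

#' Run the biomarker-discovery arm of the pipeline
#'
#' Differential expression in both matrices, p / |log2FC| filtering,
#' within-group co-expression screening restricted to the DE survivors,
#' intersection of the mRNA side with the drug-target list, median-score
#' network filtering with topological ranking, and selection of the top
#' candidate pair. All thresholds are validated before any computation.
#'
#' @param expr_lnc,expr_mrna genes x samples log2 expression matrices.
#' @param labels data.frame with `sample_id`, `response`.
#' @param targets character vector of drug-target symbols.
#' @param edges weighted edge list (`node1`, `node2`, `combined_score`).
#' @param p_de,lfc differential-expression cutoffs ([filter_de()]).
#' @param p_cor per-group correlation significance cutoff.
#' @param verbose print per-stage row counts.
#' @return list of class `discovery_report`: `de_lnc`, `de_mrna`
#'   (filtered sets with counts), `pairs` ([screen_pairs()] output),
#'   `venn`, `topology`, `ranked` (ranked candidates), `top_pair`
#'   (named character: `lnc_id`, `mrna_id`).
#' @export
run_discovery <- function(expr_lnc, expr_mrna, labels, targets, edges,
                          p_de = 0.05, lfc = 1, p_cor = 0.05,
                          verbose = FALSE) {
  check_threshold(p_de, "p_de")
  check_threshold(p_cor, "p_cor")
  if (!is.numeric(lfc) || lfc < 0) stop("invalid lfc threshold", call. = FALSE)
  say <- function(...) if (verbose) message(...)

  de_l <- filter_de(de_test(expr_lnc, labels, "lncRNA"), p_de, lfc)
  de_m <- filter_de(de_test(expr_mrna, labels, "mRNA"), p_de, lfc)
  say("DE lncRNAs: ", nrow(de_l$table), " (", de_l$n_up, " up / ",
      de_l$n_down, " down) of ", nrow(expr_lnc))
  say("DE mRNAs: ", nrow(de_m$table), " (", de_m$n_up, " up / ",
      de_m$n_down, " down) of ", nrow(expr_mrna))
  if (nrow(de_l$table) == 0L || nrow(de_m$table) == 0L)
    stop("discovery failed: no genes survive the DE filter", call. = FALSE)

  pairs <- screen_pairs(expr_lnc[de_l$table$gene_id, , drop = FALSE],
                        expr_mrna[de_m$table$gene_id, , drop = FALSE],
                        labels, p_cor)
  say("significant pairs: ", nrow(pairs$responder), " (responders), ",
      nrow(pairs$nonresponder), " (nonresponders), ",
      nrow(pairs$both), " (both)")

  it <- intersect_targets(pairs$both, targets)
  say("candidates on the target list: ", nrow(it$candidates))

  network <- filter_edges_by_median(edges)
  topo <- compute_topology(network)
  say("network after median filter: ", nrow(topo), " nodes, ",
      igraph::ecount(network), " edges")

  ranked <- select_top_pair(it$candidates, topo)
  top <- c(lnc_id = ranked$lnc_id[1], mrna_id = ranked$mrna_id[1])
  say("top pair: ", top[1], " / ", top[2])

  structure(list(de_lnc = de_l, de_mrna = de_m, pairs = pairs,
                 venn = it$venn, topology = topo, ranked = ranked,
                 top_pair = top),
            class = "discovery_report")
}

#' Train and evaluate the PLS classifier on a selected pair
#'
#' For each supplied expression matrix (one per qPCR reference-gene
#' normalization, mirroring duplicate-reference study designs), fits a
#' two-gene PLS model on the pair, runs stratified k-fold
#' cross-validation, and compares the paired-model ROC against each
#' single-gene comparator (the standardized expression of one gene alone,
#' i.e. a one-gene PLS score) with the DeLong test.
#'
#' @param expr_list named list of genes x samples matrices, or a single
#'   matrix (name used as the `reference_gene` tag of each model).
#' @param labels data.frame with `sample_id`, `response`.
#' @param pair character of length 2: the lncRNA and mRNA ids.
#' @param k cross-validation folds.
#' @param seed seed for the fold shuffle.
#' @return list of class `prediction_report`, one element per
#'   normalization: `model`, `cv`, `roc_paired`, `roc_single` (per gene),
#'   `comparisons` (per gene, [compare_roc()] vs the paired model).
#' @export
run_prediction <- function(expr_list, labels, pair, k = 5L, seed = 1L) {
  if (is.matrix(expr_list)) expr_list <- list(expression = expr_list)
  stopifnot(length(pair) >= 1L)
  out <- lapply(names(expr_list), function(ref) {
    expr <- expr_list[[ref]]
    missing <- setdiff(pair, rownames(expr))
    if (length(missing))
      stop("pair gene(s) absent from '", ref, "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    idx <- match(colnames(expr), labels$sample_id)
    y <- labels$response[idx]
    X <- t(expr[pair, , drop = FALSE])
    model <- pls_fit(X, y, reference_gene = ref)
    cv <- cross_validate(X, y, k = k, seed = seed)
    s_pair <- pls_score(model, X)
    roc_paired <- roc_auc(s_pair, y)
    singles <- lapply(pair, function(g) {
      m1 <- pls_fit(X[, g, drop = FALSE], y, reference_gene = ref)
      s1 <- pls_score(m1, X)
      list(score = s1, roc = roc_auc(s1, y),
           comparison = compare_roc(s_pair, s1, y))
    })
    names(singles) <- pair
    list(model = model, cv = cv, roc_paired = roc_paired,
         roc_single = lapply(singles, `[[`, "roc"),
         comparisons = lapply(singles, `[[`, "comparison"))
  })
  names(out) <- names(expr_list)
  class(out) <- "prediction_report"
  out
}
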