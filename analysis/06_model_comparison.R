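#!/usr/bin/env Rscript
# ROC comparison of the paired-gene PLS score against each single-gene
# score (DeLong test), per reference-gene normalization, plus ROC point
# export for plotting.

library(plspair)

dat <- "results/data"
pair <- read_gene_list("results/selected_pair.txt")
labels <- read_labels(file.path(dat, "validation_labels.tsv"))
expr_list <- list(
  RN18S = read_expression(file.path(dat, "validation_qpcr_RN18S.tsv")),
  GAPDH = read_expression(file.path(dat, "validation_qpcr_GAPDH.tsv")))

pred <- run_prediction(expr_list, labels, pair, k = 5L, seed = 103L)

rows <- list(); roc_pts <- list()
for (ref in names(pred)) {
  p <- pred[[ref]]
  rp <- p$roc_paired
  roc_pts[[paste0("PLS_", ref)]] <-
    cbind(model = paste0("PLS_", ref), rp$points)
  for (g in pair) {
    rs <- p$roc_single[[g]]
    cmp <- p$comparisons[[g]]
    rows[[paste(ref, g)]] <- data.frame(
      reference = ref, comparator = g,
      auc_single = rs$auc, se_single = rs$se,
      ci_low = rs$ci[1], ci_high = rs$ci[2],
      auc_paired = rp$auc, delong_p = cmp$p_value)
    roc_pts[[paste(g, ref)]] <- cbind(model = paste(g, ref), rs$points)
    message(sprintf(
      "[%s] %s alone: AUC %.3f (SE %.3f, CI %.3f-%.3f) vs paired %.3f, DeLong p = %.4f",
      ref, g, rs$auc, rs$se, rs$ci[1], rs$ci[2], rp$auc, cmp$p_value))
  }
}
write.table(do.call(rbind, rows), "results/roc_comparison.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, roc_pts), "results/roc_points.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
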