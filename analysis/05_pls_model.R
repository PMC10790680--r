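#!/usr/bin/env Rscript
# Train the single-component PLS classifier on the selected pair, one
# model per qPCR reference-gene normalization of the validation-shaped
# cohort, with stratified fivefold cross-validation.

library(plspair)

dat <- "results/data"
pair <- read_gene_list("results/selected_pair.txt")
labels <- read_labels(file.path(dat, "validation_labels.tsv"))
expr_list <- list(
  RN18S = read_expression(file.path(dat, "validation_qpcr_RN18S.tsv")),
  GAPDH = read_expression(file.path(dat, "validation_qpcr_GAPDH.tsv")))

pred <- run_prediction(expr_list, labels, pair, k = 5L, seed = 103L)

cv_rows <- list()
for (ref in names(pred)) {
  p <- pred[[ref]]
  write_pls_model(p$model, sprintf("results/pls_model_%s.json", ref))
  cv_rows[[ref]] <- data.frame(
    reference = ref,
    weight_lnc = unname(p$model$weights[pair[1]]),
    weight_mrna = unname(p$model$weights[pair[2]]),
    threshold = p$model$threshold,
    cv_accuracy = p$cv$mean_accuracy,
    cv_sensitivity = p$cv$mean_sensitivity,
    cv_specificity = p$cv$mean_specificity,
    cv_auc = p$cv$mean_auc)
  message(sprintf(
    "[%s] weights (%s, %s) = (%.4f, %.4f), T = %.4f | CV: acc %.3f, sens %.3f, spec %.3f, AUC %.3f",
    ref, pair[1], pair[2], p$model$weights[pair[1]],
    p$model$weights[pair[2]], p$model$threshold, p$cv$mean_accuracy,
    p$cv$mean_sensitivity, p$cv$mean_specificity, p$cv$mean_auc))
}
write.table(do.call(rbind, cv_rows), "results/pls_cv_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
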