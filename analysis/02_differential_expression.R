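#!/usr/bin/env Rscript
# Screen lncRNAs and mRNAs differentially expressed between responders
# and nonresponders (pooled t-test, p < .05, |log2FC| >= 1).

library(plspair)

dat <- "results/data"
expr_lnc <- read_expression(file.path(dat, "discovery_lnc.tsv"))
expr_mrna <- read_expression(file.path(dat, "discovery_mrna.tsv"))
labels <- read_labels(file.path(dat, "discovery_labels.tsv"))

de_lnc <- de_test(expr_lnc, labels, "lncRNA")
de_mrna <- de_test(expr_mrna, labels, "mRNA")
f_lnc <- filter_de(de_lnc)
f_mrna <- filter_de(de_mrna)

write.table(rbind(de_lnc, de_mrna), "results/de_all.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rbind(f_lnc$table, f_mrna$table), "results/de_filtered.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message("DE lncRNAs: ", nrow(f_lnc$table), " of ", nrow(expr_lnc),
        " (", f_lnc$n_up, " up / ", f_lnc$n_down, " down)")
message("DE mRNAs:   ", nrow(f_mrna$table), " of ", nrow(expr_mrna),
        " (", f_mrna$n_up, " up / ", f_mrna$n_down, " down)")
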