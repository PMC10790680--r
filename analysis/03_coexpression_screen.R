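#!/usr/bin/env Rscript
# Pearson co-expression of every DE lncRNA x DE mRNA pair, separately
# within responders and nonresponders; keep pairs significant (p < .05)
# in both groups and intersect the mRNA side with the drug-target list.

library(plspair)

dat <- "results/data"
expr_lnc <- read_expression(file.path(dat, "discovery_lnc.tsv"))
expr_mrna <- read_expression(file.path(dat, "discovery_mrna.tsv"))
labels <- read_labels(file.path(dat, "discovery_labels.tsv"))
targets <- read_gene_list(file.path(dat, "drug_targets.txt"))
de <- read.delim("results/de_filtered.tsv", stringsAsFactors = FALSE)

lnc_ids <- de$gene_id[de$gene_class == "lncRNA"]
mrna_ids <- de$gene_id[de$gene_class == "mRNA"]
sc <- screen_pairs(expr_lnc[lnc_ids, , drop = FALSE],
                   expr_mrna[mrna_ids, , drop = FALSE], labels)
it <- intersect_targets(sc$both, targets)

write.table(sc$both, "results/pairs_both_groups.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(it$candidates, "results/candidate_pairs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message("significant pairs: ", nrow(sc$responder), " (responders), ",
        nrow(sc$nonresponder), " (nonresponders), ",
        nrow(sc$both), " (both groups)")
message("on the ", it$venn["targets"], "-gene target list: ",
        nrow(it$candidates), " candidate pair(s), ",
        it$venn["overlap"], " distinct target mRNA(s)")
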