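#!/usr/bin/env Rscript
# Simulate the study inputs: a discovery cohort (20 responders / 20
# nonresponders, planted lncRNA/mRNA pair with opposite-direction shifts
# and within-class correlation 0.8), a validation-shaped cohort (25/15),
# a weighted interaction network with the planted genes as hubs, and a
# 57-gene drug-target list containing the planted mRNA.

library(plspair)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 101L)
st <- simulate_study(cfg)
ch <- st$cohort

write_expression(ch$expr_lnc, file.path(out, "discovery_lnc.tsv"))
write_expression(ch$expr_mrna, file.path(out, "discovery_mrna.tsv"))
write_labels(ch$labels, file.path(out, "discovery_labels.tsv"))
write_edges(st$edges, file.path(out, "network_edges.tsv"))
write_gene_list(st$targets, file.path(out, "drug_targets.txt"))
write_gene_list(c(ch$truth$signal_lnc_id, ch$truth$signal_mrna_id),
                file.path(out, "planted_pair.txt"))

vcfg <- sim_config(n_responders = 25L, n_nonresponders = 15L, seed = 102L)
vch <- generate_cohort(vcfg)
for (ref in c("RN18S", "GAPDH"))
  write_expression(qpcr_matrix(generate_qpcr(vch, reference_gene = ref)),
                   file.path(out, sprintf("validation_qpcr_%s.tsv", ref)))
write_labels(vch$labels, file.path(out, "validation_labels.tsv"))

message("discovery cohort: ", nrow(ch$expr_lnc), " lncRNAs + ",
        nrow(ch$expr_mrna), " mRNAs x ", nrow(ch$labels), " samples")
message("planted pair: ", ch$truth$signal_lnc_id, " / ",
        ch$truth$signal_mrna_id)
message("network: ", nrow(st$edges), " edges; targets: ",
        length(st$targets), " symbols")
message("validation cohort: ", nrow(vch$labels),
        " samples (qPCR, 2 reference genes)")
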