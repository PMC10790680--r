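#!/usr/bin/env Rscript
# Median-score filter of the interaction network, node topology (degree,
# betweenness, harmonic closeness, rank sum), and ranking of the
# candidate pairs; the top pair goes forward to the classifier.

library(plspair)

edges <- read_edges("results/data/network_edges.tsv")
cands <- read.delim("results/candidate_pairs.tsv", stringsAsFactors = FALSE)

network <- filter_edges_by_median(edges)
topo <- compute_topology(network)
ranked <- select_top_pair(cands, topo)

write.table(topo, "results/network_topology.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ranked, "results/ranked_pairs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gene_list(c(ranked$lnc_id[1], ranked$mrna_id[1]),
                "results/selected_pair.txt")

planted <- read_gene_list("results/data/planted_pair.txt")
message("network after median filter: ", nrow(topo), " nodes")
message("top pair: ", ranked$lnc_id[1], " / ", ranked$mrna_id[1],
        "  (mean |r| = ", round(ranked$mean_abs_r[1], 3), ")")
message("planted pair recovered: ",
        identical(c(ranked$lnc_id[1], ranked$mrna_id[1]), planted))
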