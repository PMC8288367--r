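#!/usr/bin/env Rscript
# Build the aging ligand-receptor differential communication network:
# per-cell-type scaled |log2FC| (aging vs adult) at every LR-database gene,
# edges scored as the sum of the sender-ligand and receiver-receptor
# magnitudes, filtered to the top 100 edges.

library(retinaAging)

dir.create("results", showWarnings = FALSE)
mat <- read_matrix("results/data/human")
norm <- normalize_counts(mat)
ann <- annotation_from_truth(mat)

types <- c("rod", "cone", "BC", "MG", "AC", "microglia")
mags <- lapply(setNames(types, types), function(ct) de_magnitude(norm, ann, ct))
det <- detection_fraction(norm, ann)

db <- read_lr_pairs(system.file("extdata", "lr_pairs.tsv",
                                package = "retinaAging"))
net <- build_network(db, mags, det[, types], expr_filter = 0.10)
message(sprintf("candidate edges passing the 10%% detection gate: %d",
                nrow(net$edges)))
top <- top_k_edges(net, 100)
write_comm_edges(top, "results/comm_edges_human.tsv")
message("top 5 edges by summed scaled DE magnitude:")
print(head(top$edges[, c("pair_id", "sender", "receiver", "score")], 5),
      row.names = FALSE)
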