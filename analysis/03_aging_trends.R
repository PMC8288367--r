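#!/usr/bin/env Rscript
# Screen for genes that rise or fall monotonically across the adult ->
# mid-age -> aging stages in the simulated human retina, and profile the
# detected genes per cell type relative to the adult stage.

library(retinaAging)

dir.create("results", showWarnings = FALSE)
mat <- read_matrix("results/data/human")
norm <- normalize_counts(mat)

trends <- detect_monotone_genes(norm, alpha = 0.05, min_log2fc = 0.25)
write.table(trends, "results/trends_human.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
n_up <- sum(trends$direction == "up")
n_down <- sum(trends$direction == "down")
message(sprintf("monotone screen: %d up-regulated, %d down-regulated of %d tested",
                n_up, n_down, nrow(trends)))

truth <- read.delim("results/data/human/truth.tsv")
cfgy <- yaml::read_yaml("results/data/human/config.yaml")
message(sprintf("planted: %d up, %d down; recovered exactly: %s",
                length(cfgy$up_genes), length(cfgy$down_genes),
                setequal(trends$gene[trends$direction == "up"], unlist(cfgy$up_genes)) &&
                  setequal(trends$gene[trends$direction == "down"], unlist(cfgy$down_genes))))

# per-cell-type stage fold changes for the top detected genes
ann <- annotation_from_truth(mat)
genes <- head(trends$gene[trends$direction == "up"], 10)
fc <- celltype_stage_foldchange(norm, ann, genes)
fc_tab <- as.data.frame.table(fc, responseName = "log2fc")
names(fc_tab)[1:3] <- c("gene", "cell_type", "stage")
write.table(fc_tab, "results/trend_foldchanges_human.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("aging-stage log2FC (mean over top 10 up-genes, by cell type):")
print(round(apply(fc[, , "aging"], 2, mean), 2))
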