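#!/usr/bin/env Rscript
# Differential expression: the same exact NB machinery applied to
# gene-level counts, DE at FDR < 0.05 split by direction, plus RPKM
# (3'UTR-excluded effective lengths).
# run from the repository root: Rscript analysis/04_expression.R
source("analysis/00_common.R")

tab <- read.delim(file.path(DATA_DIR, "expression_counts.tsv"))
counts <- as.matrix(tab[, -1])
rownames(counts) <- tab$gene_id
gm <- read_gene_models(file.path(DATA_DIR, "genes.tsv"))
cond <- ifelse(grepl("untreated", colnames(counts)), "untreated", "induced")

cm <- count_matrix(counts, condition = cond,
                   features = data.frame(gene_id = rownames(counts)))
de <- de_genes(cm)
message(length(de$up) + length(de$down), " DE genes at FDR < 0.05 (",
        length(de$up), " up, ", length(de$down), " down)")

truth_up <- readLines(file.path(DATA_DIR, "truth_de_up.txt"))
message(sprintf("recall of planted DE genes: %.1f%%",
                100 * length(intersect(de$up, truth_up)) / length(truth_up)))

eff_len <- exonic_length(gm, exclude_utr3 = TRUE)
rpkm_mat <- vapply(seq_len(ncol(counts)), function(j) {
  rpkm(counts[, j], eff_len[rownames(counts)], sum(counts[, j]))
}, numeric(nrow(counts)))
colnames(rpkm_mat) <- colnames(counts)

out <- cbind(de$result$table, round(rpkm_mat, 2))
write.table(out, file.path(RESULTS, "expression_diff.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(de$up, file.path(RESULTS, "de_genes_up.txt"))
writeLines(de$down, file.path(RESULTS, "de_genes_down.txt"))
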