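#!/usr/bin/env Rscript
# Region--gene association: annotate regions against genic elements, then
# run both permutation tests — forward (nearest genes of differential
# regions vs DE genes, 100,000 permutations) and reverse (DE genes with a
# differential region within 20 kb of the gene span, 1,000 permutations).
# run from the repository root: Rscript analysis/05_association.R
source("analysis/00_common.R")

gm <- read_gene_models(file.path(DATA_DIR, "genes.tsv"))
universe <- gm$genes$gene_id
up <- readLines(file.path(RESULTS, "de_genes_up.txt"))
union <- read_bed(file.path(RESULTS, "union_dhs.bed"))
loose_inc <- read_bed(file.path(RESULTS, "delta_loose_increase.bed"))

for (nm in c("union DHS", "loose increase")) {
  regions <- if (nm == "union DHS") union else loose_inc
  ann <- annotate_regions(regions, gm)
  message(nm, " category fractions:")
  print(round(ann$fractions, 3))
}

ng <- nearest_gene(loose_inc, gm)
fwd <- permutation_enrichment(unique(ng$gene_id), up, universe,
                              N = 100000, seed = SEED)
message(sprintf(
  "forward test: observed %d DE genes among nearest genes (null mean %.1f) -> p_enrich = %.2g",
  fwd$observed, mean(fwd$null), fwd$p_enrich))

rev <- reverse_association(up, loose_inc, gm, window = 20000, N = 1000,
                           seed = SEED)
message(sprintf(
  "reverse test: %d of %d upregulated genes have an increase within 20 kb (null mean %.1f) -> p_enrich = %.2g",
  rev$observed, length(up), mean(rev$null), rev$p_enrich))

out <- data.frame(
  test = c("forward_nearest_gene", "reverse_20kb_window"),
  observed = c(fwd$observed, rev$observed),
  null_mean = c(mean(fwd$null), mean(rev$null)),
  p_enrich = c(fwd$p_enrich, rev$p_enrich),
  p_deplete = c(fwd$p_deplete, rev$p_deplete),
  n_perm = c(fwd$N, rev$N)
)
write.table(out, file.path(RESULTS, "association.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
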