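#!/usr/bin/env Rscript
# Simulate the study: replicate per-base DNase cut profiles for untreated
# and hormone-induced conditions, genomic sequence with planted receptor
# motifs, and gene-level expression counts. Ground truth (DHS, planted
# accessibility increases, motif sites, emulated ChIP peaks) is written
# alongside so later scripts can score themselves against it.
# run from the repository root: Rscript analysis/01_simulate.R
source("analysis/00_common.R")

message("Scenario: ", format(scenario$L, big.mark = ","), " bp, ",
        nrow(scenario$dhs), " DHS, ",
        sum(scenario$delta$direction == "increase"),
        " planted increases (fold ", scenario$fold, "), ",
        nrow(scenario$motif_sites), " motif sites, seed ", SEED)

for (p in simulate_all_cuts(scenario)) {
  write_bedgraph(p, path_profile(p$replicate))
  message("  wrote ", p$replicate, ": ",
          format(total_cuts(p), big.mark = ","), " cuts")
}

write_fasta(simulate_sequence(scenario, pwm),
            file.path(DATA_DIR, "genome.fasta"))
write_gene_models(scenario$genes, file.path(DATA_DIR, "genes.tsv"))
writeLines(scenario$genes$genes$gene_id[scenario$genes$genes$de],
           file.path(DATA_DIR, "truth_de_up.txt"))

expr <- simulate_expression(scenario)
write.table(data.frame(gene_id = rownames(expr$counts), expr$counts),
            file.path(DATA_DIR, "expression_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

write_bed(scenario$dhs[, c("chrom", "start", "end", "name")],
          file.path(DATA_DIR, "truth_dhs.bed"))
write_bed(scenario$delta[, c("chrom", "start", "end", "name")],
          file.path(DATA_DIR, "truth_delta_increase.bed"))
write_bed(scenario$motif_sites[, c("chrom", "start", "end", "name",
                                   "strand")],
          file.path(DATA_DIR, "truth_motif_sites.bed"))
write_bed(scenario_ar_peaks(scenario),
          file.path(DATA_DIR, "ar_peaks_synthetic.bed"))
message("Simulation artifacts written under ", DATA_DIR)
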