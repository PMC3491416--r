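#!/usr/bin/env Rscript
# Base-pair-resolution footprints: aggregate cut profile around bound
# motif sites, 31-bp per-site vectors, repeated k-means with cross-run
# matched-correlation stability, stability comparison between conditions,
# and the stability-guided choice of k.
# run from the repository root: Rscript analysis/07_footprints.R
source("analysis/00_common.R")

profiles <- load_profiles()
conds <- vapply(profiles, function(p) p$condition, "")
pooled <- list(untreated = pool_profiles(profiles[conds == "untreated"]),
               induced = pool_profiles(profiles[conds == "induced"]))

matches <- read_bed(file.path(RESULTS, "motif_matches.bed"))
ar_peaks <- read_bed(file.path(DATA_DIR, "ar_peaks_synthetic.bed"))
peaks_i <- read_bed(file.path(RESULTS, "peaks_induced.bed"))
ar_dhs <- peaks_i[IRanges::overlapsAny(
  GenomicRanges::GRanges(peaks_i$chrom,
                         IRanges::IRanges(peaks_i$start + 1, peaks_i$end)),
  GenomicRanges::GRanges(ar_peaks$chrom,
                         IRanges::IRanges(ar_peaks$start + 1, ar_peaks$end))
), ]
sites <- best_match_per_region(matches, ar_dhs)
message(nrow(sites), " representative bound motif sites")

stab <- list()
for (cond in c("untreated", "induced")) {
  agg <- aggregate_profile(pooled[[cond]], sites, flank = 100)
  write.table(
    data.frame(position = seq_along(agg) - 108L, cuts = agg),
    file.path(RESULTS, sprintf("aggregate_profile_%s.tsv", cond)),
    sep = "\t", quote = FALSE, row.names = FALSE)
  fm <- footprint_matrix(pooled[[cond]], sites)
  stab[[cond]] <- kmeans_stability(fm, k = 3, runs = 100,
                                   seed = derive_seed(SEED, cond),
                                   row_normalize = TRUE)
  message(sprintf("  %s stability: median %.3f, mean %.3f",
                  cond, stab[[cond]]$median, stab[[cond]]$mean))
}

cmp <- compare_stability(stab$induced, stab$untreated,
                         "induced", "untreated")
message(sprintf(
  "stability comparison: %s side higher, Mann-Whitney p = %.3g",
  cmp$higher, cmp$p_value))

fm_i <- footprint_matrix(pooled$induced, sites)
ks <- select_k(fm_i, k_range = 2:5, runs = 100, seed = SEED,
               row_normalize = TRUE)
message("stability by k:")
print(round(ks$summary, 3))
message("recommended k = ", ks$recommended_k)

write.table(as.data.frame(consensus_centers(stab$induced)),
            file.path(RESULTS, "footprint_centers_induced.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ks$summary, file.path(RESULTS, "k_selection.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
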