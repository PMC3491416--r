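#!/usr/bin/env Rscript
# Differential accessibility: union the two conditions' DHS peaks, tile
# with overlapping 300-bp windows, count replicate tags, run the exact NB
# test, and merge significant windows into strict (FDR < 0.05) and loose
# (raw p < 0.05) increase/decrease region sets. Also computes the
# normalized differential tag score per union region.
# run from the repository root: Rscript analysis/03_delta_dnase.R
source("analysis/00_common.R")

profiles <- load_profiles()
peaks_u <- read_bed(file.path(RESULTS, "peaks_untreated.bed"))
peaks_i <- read_bed(file.path(RESULTS, "peaks_induced.bed"))

union <- union_regions(peaks_u, peaks_i)
write_bed(union, file.path(RESULTS, "union_dhs.bed"))
windows <- tile_regions(union)
message(nrow(union), " union regions -> ", nrow(windows), " windows")

cm <- count_and_filter(windows, profiles)
message(nrow(cm$counts), " windows kept after the <5-read filter")
res <- nb_exact_test(cm)
message(sprintf("common dispersion: %.4f", res$dispersion))
write.table(res$table, file.path(RESULTS, "window_diff.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sets <- classify_and_merge(res)
print(sets)
truth <- read_bed(file.path(DATA_DIR, "truth_delta_increase.bed"))
message(sprintf("loose recall of planted increases: %.1f%%",
                100 * overlap_fraction(truth, sets$loose_increase)$frac_a))
for (nm in c("strict_increase", "loose_increase",
             "strict_decrease", "loose_decrease")) {
  if (nrow(sets[[nm]])) {
    write_bed(sets[[nm]][, c("chrom", "start", "end", "name")],
              file.path(RESULTS, sprintf("delta_%s.bed", nm)))
  }
}

union$diff_score <- normalized_differential_score(union, profiles)
write.table(union[, c("chrom", "start", "end", "name", "diff_score")],
            file.path(RESULTS, "union_diff_score.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("differential tag score: %d regions positive, %d negative",
                sum(union$diff_score > 0), sum(union$diff_score < 0)))
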