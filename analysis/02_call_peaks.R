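#!/usr/bin/env Rscript
# Call DNase I hypersensitive sites per condition: pool replicates, smooth
# cuts into a continuous signal, fit a gamma to the positive signal and
# threshold at the P < 0.05 upper tail. Reports recovery against the
# planted DHS truth and the between-condition peak overlap.
# run from the repository root: Rscript analysis/02_call_peaks.R
source("analysis/00_common.R")

profiles <- load_profiles()
conds <- vapply(profiles, function(p) p$condition, "")
truth <- read_bed(file.path(DATA_DIR, "truth_dhs.bed"))

peaks <- list()
for (cond in c("untreated", "induced")) {
  pooled <- pool_profiles(profiles[conds == cond])
  res <- call_dhs(pooled)
  peaks[[cond]] <- res$peaks
  write_peaks_bed(res$peaks,
                  file.path(RESULTS, sprintf("peaks_%s.bed", cond)))
  rec <- overlap_fraction(truth, res$peaks)
  prec <- overlap_fraction(res$peaks, truth)
  message(sprintf(
    "%s: threshold %.3f, %d peaks; truth recall %.1f%%, precision %.1f%%",
    cond, res$threshold, nrow(res$peaks), 100 * rec$frac_a, 100 * prec$frac_a))
}

ov <- overlap_fraction(peaks$untreated, peaks$induced)
message(sprintf(
  "peak overlap: %.1f%% of untreated sites / %.1f%% of induced sites",
  100 * ov$frac_a, 100 * ov$frac_b))
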