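#!/usr/bin/env Rscript
# Motif analysis: first-order log-likelihood scan of the union DHS space
# at the 90th-percentile score threshold, recovery of planted sites, and
# the relative enrichment of the motif in differential versus unchanged
# DHS regions.
# run from the repository root: Rscript analysis/06_motif_scan.R
source("analysis/00_common.R")

seqs <- read_fasta(file.path(DATA_DIR, "genome.fasta"))
union <- read_bed(file.path(RESULTS, "union_dhs.bed"))
matches <- scan_sequence(seqs, pwm, percentile = 90, mask = union)
message(nrow(matches), " matches at the 90th-percentile threshold (",
        sprintf("%.2f", attr(matches, "threshold")), " log-likelihood)")

truth <- read_bed(file.path(DATA_DIR, "truth_motif_sites.bed"))
hit <- vapply(seq_len(nrow(truth)), function(i) {
  any(matches$start == truth$start[i])
}, TRUE)
message(sprintf("planted-site recovery: %.1f%%", 100 * mean(hit)))

out <- matches
out$score <- round(out$score * 100)
write_bed(out, file.path(RESULTS, "motif_matches.bed"))

loose_inc <- read_bed(file.path(RESULTS, "delta_loose_increase.bed"))
other <- union[!IRanges::overlapsAny(
  GenomicRanges::GRanges(union$chrom,
                         IRanges::IRanges(union$start + 1, union$end)),
  GenomicRanges::GRanges(loose_inc$chrom,
                         IRanges::IRanges(loose_inc$start + 1, loose_inc$end))
), ]
re <- relative_enrichment(matches, loose_inc, other)
message(sprintf(
  "relative enrichment in increases vs other DHS: %.2f (%.0f%% vs %.0f%% of regions with a match)",
  re$score, 100 * re$frac_a, 100 * re$frac_b))
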