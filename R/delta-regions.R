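#' Classify significant windows and merge them into differential regions
#'
#' Windows passing each threshold are split by direction and merged into
#' regions when they overlap or are book-ended (tiling-adjacent windows are
#' neighbors); windows moving in opposite directions are never merged.
#' Because the BH adjustment never lowers a p-value, the strict (FDR)
#' region sets are nested within the loose (raw p) sets.
#'
#' @param results A `diff_result` over tiled windows (see
#'   [nb_exact_test()]).
#' @param strict_fdr Strict threshold on BH-adjusted FDR (default 0.05).
#' @param loose_p Loose threshold on unadjusted p-values (default 0.05).
#' @return An object of class `delta_region_sets`: list with interval
#'   `data.frame`s `strict_increase`, `loose_increase`, `strict_decrease`,
#'   `loose_decrease` (each region scored by `pvalue` = min window p) and
#'   the thresholds used.
#' @export
classify_and_merge <- function(results, strict_fdr = 0.05, loose_p = 0.05) {
  stopifnot(inherits(results, "diff_result"))
  tab <- results$table
  stopifnot(all(c("chrom", "start", "end") %in% names(tab)))
  merge_set <- function(keep) {
    sub <- tab[keep, , drop = FALSE]
    if (nrow(sub) == 0L) {
      out <- genomic_intervals(character(), integer(), integer())
      out$pvalue <- numeric(0)
      return(out)
    }
    gr <- as_granges(sub[, c("chrom", "start", "end")])
    GenomicRanges::strand(gr) <- "*"
    red <- GenomicRanges::reduce(BiocGenerics::sort(gr))
    hits <- GenomicRanges::findOverlaps(gr, red)
    minp <- tapply(sub$pvalue[S4Vectors::queryHits(hits)],
                   S4Vectors::subjectHits(hits), min)
    out <- from_granges(red)
    out$pvalue <- as.numeric(minp[as.character(seq_len(nrow(out)))])
    out$name <- sprintf("region_%d", seq_len(nrow(out)))
    out
  }
  sets <- list(
    strict_increase = merge_set(tab$fdr < strict_fdr & tab$logFC > 0),
    loose_increase = merge_set(tab$pvalue < loose_p & tab$logFC > 0),
    strict_decrease = merge_set(tab$fdr < strict_fdr & tab$logFC < 0),
    loose_decrease = merge_set(tab$pvalue < loose_p & tab$logFC < 0)
  )
  structure(c(sets, list(strict_fdr = strict_fdr, loose_p = loose_p)),
            class = "delta_region_sets")
}

#' @export
print.delta_region_sets <- function(x, ...) {
  cat(sprintf(paste0(
    "<delta_region_sets> strict increase %d, loose increase %d, ",
    "strict decrease %d, loose decrease %d\n"),
    nrow(x$strict_increase), nrow(x$loose_increase),
    nrow(x$strict_decrease), nrow(x$loose_decrease)))
  invisible(x)
}
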