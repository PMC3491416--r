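#' Count sequence tags per gene
#'
#' A tag is assigned to a gene when its 5' base (interval start for `+`/`.`
#' tags, `end - 1` for `-` tags) lies within any exon of that gene. A tag
#' falling in the exons of several overlapping genes is counted for each of
#' them.
#'
#' @param gm A `gene_models`.
#' @param tags Interval `data.frame` of aligned tags.
#' @param exclude_utr3 Drop tags whose 5' base falls in the gene's 3'UTR
#'   (used for RPKM; default `FALSE`).
#' @return Named numeric vector of counts per gene (all genes, zeros
#'   included).
#' @export
gene_counts <- function(gm, tags, exclude_utr3 = FALSE) {
  stopifnot(inherits(gm, "gene_models"))
  validate_intervals(tags)
  out <- stats::setNames(rep(0, nrow(gm$genes)), gm$genes$gene_id)
  if (nrow(tags) == 0L) return(out)
  pos <- ifelse(tags$strand == "-", tags$end - 1L, tags$start)
  pts <- GenomicRanges::GRanges(tags$chrom,
                                IRanges::IRanges(pos + 1L, width = 1L))
  ex <- GenomicRanges::GRanges(gm$exons$chrom,
                               IRanges::IRanges(gm$exons$start + 1L,
                                                gm$exons$end))
  hits <- GenomicRanges::findOverlaps(pts, ex)
  if (length(hits) == 0L) return(out)
  hit_gene <- gm$exons$gene_id[S4Vectors::subjectHits(hits)]
  hit_tag <- S4Vectors::queryHits(hits)
  # a tag hitting two exons of the same gene still counts once
  keep <- !duplicated(paste(hit_tag, hit_gene))
  hit_gene <- hit_gene[keep]; hit_tag <- hit_tag[keep]
  if (exclude_utr3 && !is.null(gm$utr3)) {
    m <- match(hit_gene, gm$utr3$gene_id)
    p <- pos[hit_tag]
    in_utr <- !is.na(m) & p >= gm$utr3$start[m] & p < gm$utr3$end[m]
    hit_gene <- hit_gene[!in_utr]
  }
  tab <- table(hit_gene)
  out[names(tab)] <- as.numeric(tab)
  out
}

#' Reads per kilobase of model per million mapped reads
#'
#' `RPKM = count * 1e9 / (library_size * effective_length)`, where the
#' effective length is the exonic length excluding the 3'UTR (see
#' [exonic_length()]) and the counts should likewise exclude 3'UTR tags
#' (see [gene_counts()] with `exclude_utr3 = TRUE`).
#'
#' @param counts Numeric vector of per-gene tag counts.
#' @param effective_length Numeric vector of effective lengths in bp.
#' @param library_size Total mapped tags in the replicate.
#' @return Numeric vector of RPKM values.
#' @export
rpkm <- function(counts, effective_length, library_size) {
  stopifnot(library_size > 0)
  if (any(effective_length <= 0)) {
    dd_stop("rpkm: zero or negative effective length")
  }
  counts * 1e9 / (library_size * effective_length)
}

#' Call differentially expressed genes
#'
#' Applies the window-level exact negative-binomial machinery
#' ([nb_exact_test()]) to a gene-level count matrix and splits significant
#' genes by fold-change sign.
#'
#' @param cm A `count_matrix` of gene counts (both conditions).
#' @param fdr DE threshold on BH-adjusted FDR (default 0.05).
#' @return List with `result` (the `diff_result`), `up` and `down`
#'   (character vectors of gene ids) and `fdr`.
#' @export
de_genes <- function(cm, fdr = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  res <- nb_exact_test(cm)
  tab <- res$table
  ids <- if ("gene_id" %in% names(tab)) tab$gene_id else rownames(cm$counts)
  sig <- tab$fdr < fdr
  list(result = res,
       up = ids[sig & tab$logFC > 0],
       down = ids[sig & tab$logFC < 0],
       fdr = fdr)
}
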