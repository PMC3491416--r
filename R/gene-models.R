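#' Gene models
#'
#' Minimal gene models for tag counting, RPKM and region annotation: per
#' gene a span, strand, TSS, a set of non-overlapping exons and an optional
#' 3' untranslated region.
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `start`, `end` (gene span, 0-based half-open), `tss`
#'   (0-based position, inside the span).
#' @param exons `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end`; exons of one gene must be non-overlapping once sorted.
#' @param utr3 Optional `data.frame` with columns `gene_id`, `chrom`,
#'   `start`, `end` (one row per gene at most).
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, exons, utr3 = NULL) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end", "tss")
                %in% names(genes)),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
  genes <- as.data.frame(genes); exons <- as.data.frame(exons)
  if (anyDuplicated(genes$gene_id)) dd_stop("gene_models: duplicated gene_id")
  if (!all(genes$strand %in% c("+", "-"))) {
    dd_stop("gene_models: gene strand must be '+' or '-'")
  }
  bad <- genes$tss < genes$start | genes$tss >= genes$end
  if (any(bad)) {
    dd_stop("gene_models: TSS outside gene span for ",
            genes$gene_id[bad][1L])
  }
  if (!all(exons$gene_id %in% genes$gene_id)) {
    dd_stop("gene_models: exon with unknown gene_id")
  }
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  for (g in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == g, ]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
      dd_stop("gene_models: overlapping exons in ", g)
    }
  }
  if (!is.null(utr3)) {
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(utr3)))
    utr3 <- as.data.frame(utr3)
  }
  structure(list(genes = genes, exons = exons, utr3 = utr3),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d gene(s), %d exon(s)\n",
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Write gene models to a single TSV
#'
#' One row per gene with comma-separated exon starts/ends (BED12-like, all
#' coordinates 0-based half-open).
#'
#' @param gm A `gene_models`.
#' @param path Output path.
#' @export
write_gene_models <- function(gm, path) {
  stopifnot(inherits(gm, "gene_models"))
  g <- gm$genes
  ex_start <- ex_end <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    e <- gm$exons[gm$exons$gene_id == g$gene_id[i], ]
    ex_start[i] <- paste(e$start, collapse = ",")
    ex_end[i] <- paste(e$end, collapse = ",")
  }
  u_start <- u_end <- rep(NA_integer_, nrow(g))
  if (!is.null(gm$utr3)) {
    m <- match(g$gene_id, gm$utr3$gene_id)
    u_start <- gm$utr3$start[m]; u_end <- gm$utr3$end[m]
  }
  out <- data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                    start = g$start, end = g$end, tss = g$tss,
                    exon_starts = ex_start, exon_ends = ex_end,
                    utr3_start = u_start, utr3_end = u_end)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models written by [write_gene_models()]
#' @param path TSV path.
#' @return A `gene_models`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) dd_stop("read_gene_models: file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(gene_id = tab$gene_id[i], chrom = tab$chrom[i],
               start = as.integer(strsplit(tab$exon_starts[i], ",")[[1L]]),
               end = as.integer(strsplit(tab$exon_ends[i], ",")[[1L]]))
  }))
  utr3 <- NULL
  if ("utr3_start" %in% names(tab) && any(!is.na(tab$utr3_start))) {
    keep <- !is.na(tab$utr3_start)
    utr3 <- data.frame(gene_id = tab$gene_id[keep], chrom = tab$chrom[keep],
                       start = as.integer(tab$utr3_start[keep]),
                       end = as.integer(tab$utr3_end[keep]))
  }
  gene_models(tab[, c("gene_id", "chrom", "strand", "start", "end", "tss")],
              exons, utr3)
}

#' Exonic length per gene
#'
#' Total exonic base pairs per gene, optionally excluding base pairs that
#' fall in the 3'UTR — the effective length used by [rpkm()].
#'
#' @param gm A `gene_models`.
#' @param exclude_utr3 Subtract exon/3'UTR overlap (default `TRUE`).
#' @return Named numeric vector of lengths (bp) per gene.
#' @export
exonic_length <- function(gm, exclude_utr3 = TRUE) {
  stopifnot(inherits(gm, "gene_models"))
  len <- tapply(gm$exons$end - gm$exons$start, gm$exons$gene_id, sum)
  out <- stats::setNames(rep(0, nrow(gm$genes)), gm$genes$gene_id)
  out[names(len)] <- len
  if (exclude_utr3 && !is.null(gm$utr3)) {
    for (i in seq_len(nrow(gm$utr3))) {
      g <- gm$utr3$gene_id[i]
      e <- gm$exons[gm$exons$gene_id == g, ]
      ov <- pmax(0, pmin(e$end, gm$utr3$end[i]) - pmax(e$start, gm$utr3$start[i]))
      out[g] <- out[g] - sum(ov)
    }
  }
  out
}
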