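#' Assign regions to gene-relative categories
#'
#' Each region, represented by its midpoint, gets exactly one category by
#' fixed precedence: promoter (within `promoter` bp upstream of a TSS,
#' strand-aware) > first exon/intron > other intragenic > 3'-proximal
#' (within `promoter` bp downstream of a gene end) > intergenic.
#'
#' @param regions Interval `data.frame`.
#' @param gm A `gene_models`.
#' @param promoter Promoter (and 3'-proximal) window size in bp
#'   (default 2000).
#' @return List with `counts` and `fractions` (named over the five
#'   categories; fractions sum to 1) and `category` (per-region factor).
#' @export
annotate_regions <- function(regions, gm, promoter = 2000L) {
  validate_intervals(regions)
  stopifnot(inherits(gm, "gene_models"), promoter > 0)
  cats <- c("promoter", "first_exon_intron", "other_intragenic",
            "utr3_proximal", "intergenic")
  if (nrow(regions) == 0L) {
    z <- stats::setNames(rep(0L, 5L), cats)
    return(list(counts = z, fractions = z, category = factor(character(),
                                                             levels = cats)))
  }
  g <- gm$genes
  mk <- function(chrom, start, end) {
    keep <- end > start
    GenomicRanges::GRanges(chrom[keep],
                           IRanges::IRanges(start[keep] + 1L, end[keep]))
  }
  prom <- mk(g$chrom,
             ifelse(g$strand == "+", g$tss - promoter, g$tss + 1L),
             ifelse(g$strand == "+", g$tss, g$tss + 1L + promoter))
  # first exon and first intron in transcription order
  fe <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    e <- gm$exons[gm$exons$gene_id == g$gene_id[i], ]
    e <- e[order(e$start), ]
    if (nrow(e) == 0L) return(NULL)
    if (g$strand[i] == "+") {
      fx <- c(e$start[1L], e$end[1L])
      fi <- if (nrow(e) > 1L) c(e$end[1L], e$start[2L]) else NULL
    } else {
      fx <- c(e$start[nrow(e)], e$end[nrow(e)])
      fi <- if (nrow(e) > 1L) c(e$end[nrow(e) - 1L], e$start[nrow(e)]) else NULL
    }
    rbind(data.frame(chrom = g$chrom[i], start = fx[1L], end = fx[2L]),
          if (!is.null(fi)) data.frame(chrom = g$chrom[i], start = fi[1L],
                                       end = fi[2L]))
  }))
  first_ei <- mk(fe$chrom, fe$start, fe$end)
  span <- mk(g$chrom, g$start, g$end)
  down <- mk(g$chrom,
             ifelse(g$strand == "+", g$end, g$start - promoter),
             ifelse(g$strand == "+", g$end + promoter, g$start))
  mid <- (regions$start + regions$end) %/% 2L
  pts <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(mid + 1L, width = 1L))
  inside <- function(gr) IRanges::overlapsAny(pts, gr)
  cat_idx <- rep(5L, nrow(regions))
  cat_idx[inside(down)] <- 4L
  cat_idx[inside(span)] <- 3L
  cat_idx[inside(first_ei)] <- 2L
  cat_idx[inside(prom)] <- 1L
  category <- factor(cats[cat_idx], levels = cats)
  counts <- table(category)
  list(counts = stats::setNames(as.integer(counts), cats),
       fractions = stats::setNames(as.numeric(counts) / nrow(regions), cats),
       category = category)
}

#' Nearest gene per region
#'
#' Distance is measured from the region midpoint to gene TSS positions;
#' equidistant ties go to the lexicographically smaller gene id.
#'
#' @param regions Interval `data.frame`.
#' @param gm A `gene_models`.
#' @return `data.frame` with one row per region: `region_name`, `gene_id`,
#'   `distance` (bp).
#' @export
nearest_gene <- function(regions, gm) {
  validate_intervals(regions)
  stopifnot(inherits(gm, "gene_models"))
  g <- gm$genes[order(gm$genes$gene_id), , drop = FALSE]
  rname <- if (!is.null(regions$name) && !any(is.na(regions$name))) {
    regions$name
  } else {
    sprintf("region_%d", seq_len(nrow(regions)))
  }
  out <- data.frame(region_name = rname,
                    gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (chrom in unique(regions$chrom)) {
    i <- which(regions$chrom == chrom)
    j <- which(g$chrom == chrom)
    if (!length(j)) {
      dd_stop("nearest_gene: regions on chromosome ", chrom,
              " but no genes there")
    }
    mid <- (regions$start[i] + regions$end[i]) %/% 2L
    d <- abs(outer(mid, g$tss[j], "-"))
    dmin <- do.call(pmin, as.data.frame(d))
    # first TRUE column per row = smallest gene_id among ties (g is sorted)
    pick <- max.col(d == dmin, ties.method = "first")
    out$gene_id[i] <- g$gene_id[j][pick]
    out$distance[i] <- dmin
  }
  out
}

#' Permutation test for region-gene set overlap (forward direction)
#'
#' Tests whether the genes nearest to a region set overlap a
#' differentially expressed gene set more (or less) than expected: each of
#' `N` permutations draws `|de_set|` genes uniformly without replacement
#' from the universe and records the overlap with `region_genes`. Both
#' one-sided p-values carry the +1 correction and so are never exactly
#' zero.
#'
#' @param region_genes Character vector: genes assigned to the regions.
#' @param de_set Character vector: DE genes; subset of `universe`.
#' @param universe Character vector of all genes.
#' @param N Number of permutations (default 100000).
#' @param seed Integer seed.
#' @return An object of class `permutation_result`: `observed`, `null`
#'   (length `N`), `p_enrich`, `p_deplete`, `N`.
#' @export
permutation_enrichment <- function(region_genes, de_set, universe,
                                   N = 100000L, seed = 1L) {
  region_genes <- unique(region_genes); de_set <- unique(de_set)
  universe <- unique(universe)
  if (!all(de_set %in% universe)) {
    dd_stop("permutation_enrichment: de_set not contained in universe")
  }
  if (!all(region_genes %in% universe)) {
    dd_stop("permutation_enrichment: region_genes not contained in universe")
  }
  k <- length(de_set); m <- length(universe)
  if (k > m) dd_stop("permutation_enrichment: |de_set| > |universe|")
  observed <- length(intersect(region_genes, de_set))
  flags <- universe %in% region_genes
  set.seed(derive_seed(seed, "perm_forward"))
  null <- vapply(seq_len(N), function(i) sum(flags[sample.int(m, k)]),
                 integer(1))
  structure(list(observed = observed, null = null,
                 p_enrich = (sum(null >= observed) + 1) / (N + 1),
                 p_deplete = (sum(null <= observed) + 1) / (N + 1),
                 N = N),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation_result> observed %d (null mean %.2f, ",
                     "N = %d): p_enrich = %.3g, p_deplete = %.3g\n"),
              x$observed, mean(x$null), x$N, x$p_enrich, x$p_deplete))
  invisible(x)
}

#' Permutation test for genes near differential regions (reverse direction)
#'
#' Counts DE genes with at least one differential region within
#' `window` bp of the gene span (isoform-merged span; a region inside the
#' span also matches) and compares against `N` random draws of equally
#' many genes.
#'
#' @param de_set Character vector of DE gene ids.
#' @param regions Interval `data.frame` of differential regions.
#' @param gm A `gene_models` (spans are the isoform-merged gene extents).
#' @param window Flanking window in bp (default 20000).
#' @param N Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A `permutation_result` with an extra `has_region` flag vector
#'   (named by gene).
#' @export
reverse_association <- function(de_set, regions, gm, window = 20000L,
                                N = 1000L, seed = 1L) {
  stopifnot(inherits(gm, "gene_models"), window >= 0)
  validate_intervals(regions)
  g <- gm$genes
  de_set <- unique(de_set)
  if (!all(de_set %in% g$gene_id)) {
    dd_stop("reverse_association: unknown DE gene id")
  }
  if (nrow(regions)) {
    spans <- GenomicRanges::GRanges(
      g$chrom,
      IRanges::IRanges(pmax(g$start - window, 0L) + 1L, g$end + window)
    )
    reg <- as_granges(regions[, c("chrom", "start", "end")])
    has_region <- IRanges::overlapsAny(spans, reg)
  } else {
    has_region <- rep(FALSE, nrow(g))
  }
  names(has_region) <- g$gene_id
  observed <- sum(has_region[de_set])
  k <- length(de_set); m <- nrow(g)
  set.seed(derive_seed(seed, "perm_reverse"))
  null <- vapply(seq_len(N), function(i) sum(has_region[sample.int(m, k)]),
                 integer(1))
  structure(list(observed = observed, null = null,
                 p_enrich = (sum(null >= observed) + 1) / (N + 1),
                 p_deplete = (sum(null <= observed) + 1) / (N + 1),
                 N = N, has_region = has_region),
            class = "permutation_result")
}
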