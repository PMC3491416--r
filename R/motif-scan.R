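#' First-order log-likelihood PWM scan
#'
#' Scores every window of PWM width on both strands as the log-likelihood
#' ratio of the PWM against a first-order (dinucleotide) background model:
#' `score = sum_j log P_pwm(base_j | j) - log P_bg(base_j | base_{j-1})`,
#' with the first base scored against the stationary background. The match
#' threshold is the `percentile` quantile of all window scores in the
#' scanned space (both strands pooled; mask-restricted when a mask is
#' given). Where both strands pass the threshold, only the stronger strand
#' is reported (ties go to `+`). Windows containing `N` are skipped.
#'
#' The default background is estimated from the scanned sequence itself
#' (pseudocount 1) and is symmetrized over strands, which makes the scan
#' strand-symmetric: scanning the reverse complement swaps strands but
#' preserves the score multiset.
#'
#' @param seqs Named character vector of sequences (chromosome -> string),
#'   or a single unnamed string (chromosome `"seq"`).
#' @param pwm A `pwm`. Zero probabilities are floored at 1e-12 for the log.
#' @param percentile Match threshold percentile over all window scores
#'   (default 90; scores >= the quantile are kept, so a constant score
#'   keeps every window).
#' @param mask Optional interval `data.frame`; only windows fully inside a
#'   mask region are scanned.
#' @param background Optional background list (see [new_pwm()]); default:
#'   [background_from_sequence()] of the scanned sequence.
#' @return Interval `data.frame` of matches with `strand` and
#'   `score`, sorted by position; attribute `threshold` holds the score
#'   cutoff.
#' @export
scan_sequence <- function(seqs, pwm, percentile = 90, mask = NULL,
                          background = NULL) {
  stopifnot(inherits(pwm, "pwm"), percentile > 0, percentile <= 100)
  if (is.null(names(seqs))) names(seqs) <- rep("seq", length(seqs))
  if (is.null(background)) {
    background <- background_from_sequence(paste(seqs, collapse = "N"))
  }
  w <- pwm$width
  lpwm <- log(pmax(pwm$mat, 1e-12))
  lstat <- log(background$stationary)
  ltrans <- log(background$transition)
  per_chrom <- list()
  for (chrom in names(seqs)) {
    code <- dna_codes(seqs[[chrom]])
    L <- length(code)
    if (L < w) next
    np <- L - w + 1L
    ok <- rep(TRUE, np)
    if (!is.null(mask)) {
      cov <- logical(L)
      msk <- mask[mask$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(msk))) {
        cov[(msk$start[i] + 1L):min(msk$end[i], L)] <- TRUE
      }
      cs <- c(0L, cumsum(cov))
      ok <- (cs[(1:np) + w] - cs[1:np]) == w
    }
    nas <- is.na(code)
    if (any(nas)) {
      cs <- c(0L, cumsum(nas))
      ok <- ok & ((cs[(1:np) + w] - cs[1:np]) == 0L)
    }
    code0 <- code; code0[nas] <- 1L  # placeholder, masked out via `ok`
    s_fwd <- numeric(np); s_rev <- numeric(np)
    lbg <- unname(lstat[code0[1:np]])
    for (j in seq_len(w)) {
      b <- code0[(1:np) + j - 1L]
      s_fwd <- s_fwd + lpwm[cbind(b, j)]
      # reverse-complement score accumulated in the orientation of the
      # reverse-complemented string (PWM column j against the complement
      # of forward position w-j+1), matching the defining sum term by term
      s_rev <- s_rev + lpwm[cbind(5L - code0[(1:np) + w - j], j)]
      # background accumulated term-by-term in scan order, so degenerate
      # PWM-equals-background scores cancel to exactly zero
      if (j > 1L) {
        lbg <- lbg + ltrans[cbind(code0[(1:np) + j - 2L], b)]
      }
    }
    per_chrom[[chrom]] <- list(pos = which(ok),
                               fwd = (s_fwd - lbg)[ok],
                               rev = (s_rev - lbg)[ok])
  }
  all_scores <- unlist(lapply(per_chrom, function(x) c(x$fwd, x$rev)),
                       use.names = FALSE)
  empty <- genomic_intervals(character(), integer(), integer())
  if (!length(all_scores)) {
    attr(empty, "threshold") <- NA_real_
    return(empty)
  }
  thr <- stats::quantile(all_scores, percentile / 100, names = FALSE)
  res <- list()
  for (chrom in names(per_chrom)) {
    x <- per_chrom[[chrom]]
    hit <- x$fwd >= thr | x$rev >= thr
    if (!any(hit)) next
    strand <- ifelse(x$fwd[hit] >= x$rev[hit], "+", "-")
    score <- pmax(x$fwd[hit], x$rev[hit])
    start <- x$pos[hit] - 1L
    res[[chrom]] <- genomic_intervals(chrom, start, start + w,
                                      strand = strand, score = score)
  }
  out <- if (length(res)) do.call(rbind, res) else empty
  rownames(out) <- NULL
  if (nrow(out)) out$name <- sprintf("match_%d", seq_len(nrow(out)))
  attr(out, "threshold") <- thr
  out
}

#' Relative motif-enrichment score between two region sets
#'
#' The relative frequency with which a motif match is found in set A
#' versus set B: `(fraction of A regions containing >= 1 match) /
#' (fraction of B regions containing >= 1 match)`. Scores above 1 mean the
#' motif is more commonly found in A.
#'
#' @param matches Interval `data.frame` of motif matches.
#' @param set_a,set_b Non-empty interval `data.frame`s of regions.
#' @return List with `score`, `frac_a`, `frac_b`.
#' @export
relative_enrichment <- function(matches, set_a, set_b) {
  validate_intervals(set_a); validate_intervals(set_b)
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) {
    dd_stop("relative_enrichment: empty region set")
  }
  frac <- function(set) {
    if (nrow(matches) == 0L) return(0)
    mean(IRanges::overlapsAny(as_granges(set[, c("chrom", "start", "end")]),
                              as_granges(matches[, c("chrom", "start", "end")])))
  }
  fa <- frac(set_a); fb <- frac(set_b)
  if (fb == 0) {
    dd_stop("relative_enrichment: no B region contains a match; ",
            "score undefined")
  }
  list(score = fa / fb, frac_a = fa, frac_b = fb)
}

#' Keep the best motif match per region
#'
#' Assigns matches to the regions they overlap and retains the
#' highest-scoring match of each region (ties: leftmost). Used to pick one
#' representative site per bound peak before footprint extraction.
#'
#' @param matches Interval `data.frame` with `score`.
#' @param regions Interval `data.frame`.
#' @return Subset of `matches`, one row per region with a match.
#' @export
best_match_per_region <- function(matches, regions) {
  validate_intervals(regions)
  if (nrow(matches) == 0L || nrow(regions) == 0L) {
    return(matches[integer(0), , drop = FALSE])
  }
  hits <- GenomicRanges::findOverlaps(
    as_granges(matches[, c("chrom", "start", "end")]),
    as_granges(regions[, c("chrom", "start", "end")])
  )
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  o <- order(s, -matches$score[q], matches$start[q])
  pick <- q[o][!duplicated(s[o])]
  out <- matches[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove motif matches with duplicated or nearby centers
#'
#' Greedy deduplication in descending score order: a match is kept when no
#' already-kept match on the same chromosome has its center closer than
#' `min_dist` bp. Intended for modest match lists (quadratic worst case).
#'
#' @param matches Interval `data.frame` with `score`.
#' @param min_dist Minimum center-to-center distance in bp (default: match
#'   width).
#' @return Deduplicated subset of `matches` in position order.
#' @export
dedupe_matches <- function(matches, min_dist = NULL) {
  if (nrow(matches) == 0L) return(matches)
  if (is.null(min_dist)) min_dist <- matches$end[1L] - matches$start[1L]
  center <- matches$start + (matches$end - matches$start) %/% 2L
  o <- order(-matches$score, matches$start)
  keep <- logical(nrow(matches))
  kept_pos <- split(numeric(0), character(0))
  for (i in o) {
    ch <- matches$chrom[i]
    kp <- kept_pos[[ch]]
    if (is.null(kp) || !any(abs(kp - center[i]) < min_dist)) {
      keep[i] <- TRUE
      kept_pos[[ch]] <- c(kp, center[i])
    }
  }
  out <- matches[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
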