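#' Feature-by-replicate count matrix
#'
#' Shared container for window-level DNase tag counts and gene-level
#' expression counts: an integer matrix (features x samples) with a
#' condition label and a library size per sample.
#'
#' @param counts Numeric matrix, features in rows, samples in columns.
#' @param condition Character vector of per-column condition labels
#'   (`"untreated"`/`"induced"`).
#' @param lib_sizes Per-column library sizes; defaults to column sums. Must
#'   be at least the column sums.
#' @param features `data.frame` describing rows (windows or genes).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition, lib_sizes = NULL,
                         features = NULL) {
  counts <- as.matrix(counts)
  stopifnot(length(condition) == ncol(counts), all(counts >= 0))
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  stopifnot(length(lib_sizes) == ncol(counts), all(lib_sizes >= 0))
  if (!is.null(features)) stopifnot(nrow(features) == nrow(counts))
  structure(list(counts = counts, condition = as.character(condition),
                 lib_sizes = as.numeric(lib_sizes), features = features),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d feature(s) x %d sample(s) [%s]\n",
              nrow(x$counts), ncol(x$counts),
              paste(x$condition, collapse = ", ")))
  invisible(x)
}

#' Count tags per window and drop near-empty windows
#'
#' Counts the tags (per-base cuts) of every replicate profile in every
#' window — a tag belongs to a window when its single base pair lies inside
#' it — and eliminates windows whose total across all replicates is below
#' `min_sum` (default: fewer than five reads).
#'
#' @param windows Interval `data.frame` (e.g. from [tile_regions()]).
#' @param profiles List of `cut_profile`s (both conditions).
#' @param min_sum Windows with row sum strictly below this are removed
#'   (default 5).
#' @return A `count_matrix` whose features are the retained windows;
#'   library sizes are the profiles' total cut counts.
#' @export
count_and_filter <- function(windows, profiles, min_sum = 5L) {
  validate_intervals(windows)
  stopifnot(length(profiles) >= 1L, min_sum >= 0)
  counts <- vapply(profiles, function(p) count_in_intervals(p, windows),
                   numeric(nrow(windows)))
  if (nrow(windows) == 1L) counts <- matrix(counts, nrow = 1L)
  colnames(counts) <- vapply(profiles, function(p) p$replicate, "")
  keep <- rowSums(counts) >= min_sum
  count_matrix(counts[keep, , drop = FALSE],
               condition = vapply(profiles, function(p) p$condition, ""),
               lib_sizes = vapply(profiles, total_cuts, numeric(1)),
               features = windows[keep, , drop = FALSE])
}

#' Normalized differential tag score per region
#'
#' For each union region, the pooled induced tag count normalized by the
#' mean pooled induced count over all regions, minus the equally normalized
#' untreated count. Positive scores mean more accessible after induction;
#' the scores average to zero over regions by construction.
#'
#' @param union Interval `data.frame` of union DHS regions.
#' @param profiles List of `cut_profile`s covering both conditions.
#' @return Numeric vector of scores, one per region.
#' @export
normalized_differential_score <- function(union, profiles) {
  validate_intervals(union)
  if (nrow(union) == 0L) dd_stop("normalized_differential_score: no regions")
  conds <- vapply(profiles, function(p) p$condition, "")
  pooled <- function(cond) {
    sel <- profiles[conds == cond]
    if (!length(sel)) dd_stop("normalized_differential_score: no ", cond,
                              " profiles")
    Reduce(`+`, lapply(sel, function(p) count_in_intervals(p, union)))
  }
  ind <- pooled("induced"); unt <- pooled("untreated")
  if (mean(ind) == 0 || mean(unt) == 0) {
    dd_stop("normalized_differential_score: zero mean tag count in a condition")
  }
  ind / mean(ind) - unt / mean(unt)
}
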