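#' Tile a region with fixed-width overlapping windows
#'
#' Implements the adaptive tiling rule used to turn union DHS regions into
#' fixed-width test windows:
#'
#' * regions no longer than `W` get a single window of width `W` centered
#'   on the region;
#' * otherwise `n = floor((len - W) / default_step) + 1` windows are placed
#'   at stride `default_step`, centered so the uncovered bases split evenly
#'   between the two edges; if each edge discards fewer than
#'   `edge_frac * len` bases these windows are kept;
#' * otherwise one more window is added and the stride recomputed as
#'   `(len - W) / n` (floored per window, with the last window pinned to
#'   the region end) so the windows exactly cover the region.
#'
#' All windows have width exactly `W`.
#'
#' @param region One-row interval `data.frame` (or a list with `chrom`,
#'   `start`, `end`).
#' @param W Window width in bp (default 300).
#' @param default_step Default stride between window starts (default 150,
#'   i.e. 50 % overlap).
#' @param edge_frac Maximum tolerated discarded fraction per edge
#'   (default 0.10).
#' @return Interval `data.frame` of windows with a `region_name` column
#'   identifying the parent region.
#' @export
tile_region <- function(region, W = 300L, default_step = 150L,
                        edge_frac = 0.10) {
  stopifnot(W > 0, default_step > 0, default_step <= W,
            edge_frac > 0, edge_frac < 1)
  W <- as.integer(W); default_step <- as.integer(default_step)
  chrom <- region$chrom[1L]
  start <- as.integer(region$start[1L]); end <- as.integer(region$end[1L])
  rname <- if (!is.null(region$name)) region$name[1L] else NA_character_
  len <- end - start
  if (len <= 0L) dd_stop("tile_region: empty region")
  if (len <= W) {
    ws <- start - (W - len) %/% 2L
    starts <- max(ws, 0L)
  } else {
    n <- (len - W) %/% default_step + 1L
    covered <- (n - 1L) * default_step + W
    left <- (len - covered) %/% 2L
    right <- len - covered - left
    if (max(left, right) < edge_frac * len) {
      starts <- start + left + (seq_len(n) - 1L) * default_step
    } else {
      # adjusted mode: n+1 windows exactly covering the region
      stride <- (len - W) / n
      offs <- as.integer(floor((0:n) * stride))
      offs[n + 1L] <- len - W
      starts <- start + offs
    }
  }
  out <- genomic_intervals(chrom, starts, starts + W)
  out$region_name <- rname
  out$name <- sprintf("%s_w%d", ifelse(is.na(rname), "region", rname),
                      seq_len(nrow(out)))
  out
}

#' Tile every region of a union set
#'
#' @param regions Interval `data.frame` (e.g. from [union_regions()]).
#' @inheritParams tile_region
#' @return Interval `data.frame` of all windows with `region_name`.
#' @export
tile_regions <- function(regions, W = 300L, default_step = 150L,
                         edge_frac = 0.10) {
  validate_intervals(regions)
  if (nrow(regions) == 0L) {
    out <- genomic_intervals(character(), integer(), integer())
    out$region_name <- character(0)
    return(out)
  }
  if (is.null(regions$name) || any(is.na(regions$name))) {
    regions$name <- sprintf("region_%d", seq_len(nrow(regions)))
  }
  pieces <- lapply(seq_len(nrow(regions)), function(i) {
    tile_region(regions[i, , drop = FALSE], W = W,
                default_step = default_step, edge_frac = edge_frac)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
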