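#' Construct a table of genomic intervals
#'
#' Intervals are the package-wide currency for peaks, windows, regions and
#' motif matches. Coordinates are 0-based half-open (`[start, end)`, the BED
#' convention) everywhere in the package.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive.
#' @param end Integer vector, 0-based exclusive; must satisfy `end > start`.
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (recycled). `"."`
#'   (unstranded) is treated as `"+"` wherever orientation matters.
#' @param score Optional numeric score (recycled).
#' @param name Optional feature name (recycled).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".",
                              score = NA_real_, name = NA_character_) {
  if (length(chrom) == 0L) {
    df <- data.frame(chrom = character(), start = integer(),
                     end = integer(), name = character(),
                     score = numeric(), strand = character(),
                     stringsAsFactors = FALSE)
    return(df)
  }
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom))) {
    dd_stop("interval validation: empty chromosome name")
  }
  if (any(df$start < 0L)) dd_stop("interval validation: start < 0")
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    dd_stop("interval validation: end <= start at row ", bad[1L])
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    dd_stop("interval validation: strand must be one of '+', '-', '.'")
  }
  invisible(df)
}

#' Convert intervals to/from GRanges
#'
#' Internal converters between the package's 0-based half-open interval
#' tables and 1-based closed [GenomicRanges::GRanges] used for interval
#' algebra.
#'
#' @param df Interval `data.frame` (see [genomic_intervals()]).
#' @return A `GRanges` with the same content.
#' @keywords internal
as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else rep(".", nrow(df))
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

from_granges <- function(gr, score = NA_real_, name = NA_character_) {
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand, score = score, name = name
  )
}

#' Read a BED file
#'
#' Reads BED3/BED6 into an interval table, preserving the file's 0-based
#' half-open coordinates as written.
#'
#' @param path Path to a tab-separated BED file (>= 3 columns).
#' @return Interval `data.frame` in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) dd_stop("read_bed: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L)) {
    dd_stop("read_bed: line ", which(n < 3L)[1L], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    dd_stop("read_bed: line ", bad[1L], ": non-integer coordinate")
  }
  bad <- which(end <= start)
  if (length(bad)) {
    dd_stop("read_bed: line ", bad[1L], ": end <= start")
  }
  name <- ifelse(n >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 NA_character_)
  score <- suppressWarnings(as.numeric(
    ifelse(n >= 5L, vapply(fields, function(f) f[min(5L, length(f))], ""), NA)
  ))
  strand <- ifelse(n >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""),
                   ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  genomic_intervals(chrom, start, end, strand = strand, score = score,
                    name = name)
}

#' Write intervals as BED
#'
#' Writes BED6 when name/score/strand carry information, BED3 otherwise.
#' Scores are written as given; see [call_peaks()] for the UCSC x1000
#' convention used for peak output.
#'
#' @param df Interval `data.frame`.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  if (is.null(df$name)) df$name <- NA_character_
  if (is.null(df$score)) df$score <- NA_real_
  if (is.null(df$strand)) df$strand <- "."
  has_extra <- nrow(df) > 0L &&
    (any(!is.na(df$name)) || any(!is.na(df$score)) || any(df$strand != "."))
  if (has_extra) {
    out <- data.frame(
      df$chrom, df$start, df$end,
      ifelse(is.na(df$name), ".", df$name),
      ifelse(is.na(df$score), 0, df$score),
      df$strand
    )
  } else {
    out <- df[, c("chrom", "start", "end")]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge two interval sets into their union
#'
#' Returns the union set of two peak/region lists: sorted, with overlapping
#' or book-ended intervals merged. This is the first step of the
#' differential-accessibility analysis, so that regions crossing the DHS
#' threshold in only one condition are still tested.
#'
#' @param a,b Interval `data.frame`s.
#' @return Sorted, non-overlapping interval `data.frame`.
#' @export
union_regions <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) + nrow(b) == 0L) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  gr <- c(as_granges(a[, c("chrom", "start", "end")]),
          as_granges(b[, c("chrom", "start", "end")]))
  GenomicRanges::strand(gr) <- "*"
  red <- GenomicRanges::reduce(BiocGenerics::sort(gr))
  out <- from_granges(red)
  out$name <- sprintf("union_%d", seq_len(nrow(out)))
  out
}

#' Overlap summary between two peak sets
#'
#' A site in one set counts as overlapping if it intersects at least one
#' base pair of the other set. Because the single overlap percentage
#' reported for two peak sets is ambiguous about its denominator, both
#' directions are reported.
#'
#' @param a,b Interval `data.frame`s.
#' @return A list with `n_a`, `n_b`, `n_a_overlapping`, `n_b_overlapping`,
#'   `frac_a` (= fraction of `a` sites overlapping `b`) and `frac_b`.
#' @export
overlap_fraction <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(list(n_a = nrow(a), n_b = nrow(b),
                n_a_overlapping = 0L, n_b_overlapping = 0L,
                frac_a = if (nrow(a)) 0 else NA_real_,
                frac_b = if (nrow(b)) 0 else NA_real_))
  }
  ga <- as_granges(a); gb <- as_granges(b)
  GenomicRanges::strand(ga) <- "*"; GenomicRanges::strand(gb) <- "*"
  na <- sum(IRanges::overlapsAny(ga, gb, minoverlap = 1L))
  nb <- sum(IRanges::overlapsAny(gb, ga, minoverlap = 1L))
  list(n_a = nrow(a), n_b = nrow(b),
       n_a_overlapping = na, n_b_overlapping = nb,
       frac_a = na / nrow(a), frac_b = nb / nrow(b))
}
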