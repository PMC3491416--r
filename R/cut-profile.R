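#' Per-base DNase I cut profile
#'
#' A cut profile stores, for one replicate of one condition, a dense vector
#' of non-negative integer DNase I 5'-cut counts per base pair, one vector
#' per chromosome. The 5' end of each sequenced fragment contributes one
#' count ("tag") at a single base, so counts are unambiguous when windows
#' overlap.
#'
#' @param cuts Named list of non-negative integer vectors, one per
#'   chromosome; the vector length is the chromosome length.
#' @param replicate Replicate identifier (character or integer).
#' @param condition Condition label, `"untreated"` or `"induced"`.
#' @return An object of class `cut_profile`.
#' @export
cut_profile <- function(cuts, replicate = "rep1", condition = "untreated") {
  stopifnot(is.list(cuts), length(cuts) > 0L, !is.null(names(cuts)))
  for (chrom in names(cuts)) {
    v <- cuts[[chrom]]
    if (any(v < 0) || any(v != floor(v))) {
      dd_stop("cut_profile: counts on ", chrom,
              " must be non-negative integers")
    }
  }
  structure(
    list(cuts = lapply(cuts, as.integer),
         chrom_sizes = vapply(cuts, length, integer(1)),
         replicate = as.character(replicate),
         condition = match.arg(condition, c("untreated", "induced"))),
    class = "cut_profile"
  )
}

#' @export
print.cut_profile <- function(x, ...) {
  cat(sprintf("<cut_profile> %s/%s: %d chromosome(s), %s cuts total\n",
              x$condition, x$replicate, length(x$cuts),
              format(total_cuts(x), big.mark = ",")))
  invisible(x)
}

#' Total number of cuts in a profile
#' @param profile A `cut_profile`.
#' @return Total tag count across all chromosomes.
#' @export
total_cuts <- function(profile) {
  stopifnot(inherits(profile, "cut_profile"))
  sum(vapply(profile$cuts, function(v) sum(as.double(v)), numeric(1)))
}

#' Pool replicate cut profiles
#'
#' Sums per-base counts across profiles (which must share chromosome
#' layout), e.g. to combine biological replicates of one condition before
#' peak calling.
#'
#' @param profiles List of `cut_profile`s.
#' @param replicate Replicate label for the pooled profile.
#' @return A `cut_profile` with summed counts.
#' @export
pool_profiles <- function(profiles, replicate = "pooled") {
  stopifnot(length(profiles) >= 1L)
  sizes <- profiles[[1L]]$chrom_sizes
  for (p in profiles) {
    stopifnot(inherits(p, "cut_profile"), identical(p$chrom_sizes, sizes))
  }
  cuts <- lapply(names(sizes), function(chrom) {
    Reduce(`+`, lapply(profiles, function(p) p$cuts[[chrom]]))
  })
  names(cuts) <- names(sizes)
  cut_profile(cuts, replicate = replicate,
              condition = profiles[[1L]]$condition)
}

#' Read per-base cut counts from a bedGraph file
#'
#' Expands 4-column bedGraph records into dense per-base vectors. Positions
#' not covered by any record are zero. Records must not overlap and must
#' fall inside the declared chromosome sizes.
#'
#' @param path bedGraph file path.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param replicate,condition Metadata for the resulting profile.
#' @return A `cut_profile`.
#' @export
read_bedgraph_cuts <- function(path, chrom_sizes, replicate = "rep1",
                               condition = "untreated") {
  if (!file.exists(path)) dd_stop("read_bedgraph_cuts: file not found: ", path)
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  cuts <- lapply(chrom_sizes, function(L) integer(L))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 4L)) {
      dd_stop("read_bedgraph_cuts: line ",
              which(lengths(fields) < 4L)[1L], ": fewer than 4 columns")
    }
    chrom <- vapply(fields, `[`, "", 1L)
    start <- as.integer(vapply(fields, `[`, "", 2L))
    end <- as.integer(vapply(fields, `[`, "", 3L))
    value <- as.numeric(vapply(fields, `[`, "", 4L))
    if (any(is.na(start) | is.na(end) | is.na(value))) {
      dd_stop("read_bedgraph_cuts: malformed record")
    }
    if (any(value < 0 | value != floor(value))) {
      dd_stop("read_bedgraph_cuts: values must be non-negative integers")
    }
    if (!all(chrom %in% names(chrom_sizes))) {
      dd_stop("read_bedgraph_cuts: record on undeclared chromosome ",
              setdiff(chrom, names(chrom_sizes))[1L])
    }
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      o <- i[order(start[i])]
      if (any(end[o] > chrom_sizes[[ch]]) || any(start[o] < 0L)) {
        dd_stop("read_bedgraph_cuts: record outside chromosome ", ch)
      }
      if (length(o) > 1L && any(start[o][-1L] < end[o][-length(o)])) {
        dd_stop("read_bedgraph_cuts: overlapping records on ", ch)
      }
      for (j in o) {
        cuts[[ch]][(start[j] + 1L):end[j]] <- as.integer(value[j])
      }
    }
  }
  cut_profile(cuts, replicate = replicate, condition = condition)
}

#' Write a cut profile as bedGraph
#'
#' Writes maximal runs of equal non-zero counts; zero runs are omitted, so
#' `read_bedgraph_cuts(write_bedgraph(p))` reproduces `p` exactly given the
#' chromosome sizes.
#'
#' @param profile A `cut_profile`.
#' @param path Output path.
#' @export
write_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "cut_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(profile$cuts)) {
    v <- profile$cuts[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0L
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%d", chrom, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}

# Tag count of each interval [start, end) in a profile, via cumulative sums.
# Internal workhorse for window counting and region scores.
count_in_intervals <- function(profile, df) {
  stopifnot(inherits(profile, "cut_profile"))
  validate_intervals(df)
  out <- numeric(nrow(df))
  for (chrom in unique(df$chrom)) {
    if (!chrom %in% names(profile$cuts)) {
      dd_stop("count_in_intervals: no profile for chromosome ", chrom)
    }
    v <- profile$cuts[[chrom]]
    i <- which(df$chrom == chrom)
    if (any(df$start[i] < 0L) || any(df$end[i] > length(v))) {
      dd_stop("count_in_intervals: interval outside chromosome ", chrom)
    }
    cs <- c(0, cumsum(as.double(v)))
    out[i] <- cs[df$end[i] + 1L] - cs[df$start[i] + 1L]
  }
  out
}
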