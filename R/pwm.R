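#' Position weight matrix with first-order background
#'
#' A PWM is a 4 x w base-probability matrix (rows A, C, G, T) together with
#' a background model used by the log-likelihood scanner: a stationary base
#' distribution and a first-order (dinucleotide) transition matrix.
#'
#' @param mat 4 x w numeric matrix of column probabilities; rows named
#'   A/C/G/T; each column must sum to 1 (tolerance 1e-9).
#' @param background List with `stationary` (length-4, sums to 1) and
#'   `transition` (4 x 4, rows sum to 1). Defaults to the uniform
#'   order-0 background (all transitions 0.25).
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(mat, background = uniform_background()) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) dd_stop("new_pwm: matrix must have 4 rows (A,C,G,T)")
  rownames(mat) <- c("A", "C", "G", "T")
  csum <- colSums(mat)
  if (any(abs(csum - 1) > 1e-9)) {
    dd_stop("new_pwm: column probabilities must sum to 1")
  }
  if (any(mat < 0)) dd_stop("new_pwm: negative probabilities")
  stopifnot(is.list(background),
            length(background$stationary) == 4L,
            all(dim(background$transition) == c(4L, 4L)))
  if (abs(sum(background$stationary) - 1) > 1e-9 ||
      any(abs(rowSums(background$transition) - 1) > 1e-9)) {
    dd_stop("new_pwm: background rows must sum to 1")
  }
  structure(list(mat = mat, width = ncol(mat), background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, consensus %s\n", x$width, pwm_consensus(x)))
  invisible(x)
}

#' Uniform first-order background
#' @return Background list with stationary = 1/4 and all transitions 1/4.
#' @export
uniform_background <- function() {
  list(stationary = stats::setNames(rep(0.25, 4), c("A", "C", "G", "T")),
       transition = matrix(0.25, 4, 4,
                           dimnames = list(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T"))))
}

#' Estimate a first-order background model from sequence
#'
#' Counts dinucleotides (with a pseudocount) over the circular closure of
#' the supplied sequence and, by default, of its reverse complement as
#' well; the stationary distribution is the row marginal of the joint
#' dinucleotide table. Circular counting plus strand symmetrization make
#' the model exactly strand-symmetric: the background probability of any
#' window equals that of its reverse complement, and the same background
#' is obtained from a sequence and from its reverse complement. Positions
#' that are not A/C/G/T are dropped before counting.
#'
#' @param seq DNA string (character scalar, A/C/G/T/N).
#' @param pseudocount Pseudocount added to every dinucleotide count
#'   (default 1).
#' @param both_strands Symmetrize over strands (default `TRUE`).
#' @return Background list (see [new_pwm()]).
#' @export
background_from_sequence <- function(seq, pseudocount = 1,
                                     both_strands = TRUE) {
  bases <- c("A", "C", "G", "T")
  code <- dna_codes(seq)
  code <- code[!is.na(code)]
  di <- matrix(0, 4, 4)
  if (length(code) > 1L) {
    a <- code
    b <- c(code[-1L], code[1L])  # circular closure: out-degree = in-degree
    di <- matrix(tabulate((a - 1L) * 4L + b, 16L), 4, 4, byrow = TRUE)
  }
  if (both_strands) {
    di <- di + t(di[4:1, 4:1])  # add reverse-complement pair counts
  }
  di <- di + pseudocount
  list(stationary = stats::setNames(rowSums(di) / sum(di), bases),
       transition = matrix(di / rowSums(di), 4, 4,
                           dimnames = list(bases, bases)))
}

#' Read a JASPAR plain-text count matrix
#'
#' Accepts the JASPAR format with four count rows (order A, C, G, T),
#' optionally prefixed by a `>` header line and with or without the
#' `A [ ... ]` row decoration. Counts plus `pseudocount` are normalized to
#' per-column probabilities.
#'
#' @param path File path.
#' @param pseudocount Pseudocount added to every count before
#'   normalization (default 0, matching the raw matrix).
#' @param background Background model attached to the PWM.
#' @return A `pwm`.
#' @export
read_jaspar_pwm <- function(path, pseudocount = 0,
                            background = uniform_background()) {
  if (!file.exists(path)) dd_stop("read_jaspar_pwm: file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  lines <- lines[!startsWith(lines, ">")]
  if (length(lines) != 4L) {
    dd_stop("read_jaspar_pwm: expected 4 count rows, found ", length(lines))
  }
  rows <- lapply(lines, function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("[][]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  })
  if (length(unique(lengths(rows))) != 1L) {
    dd_stop("read_jaspar_pwm: rows of unequal length")
  }
  counts <- do.call(rbind, rows)
  if (any(is.na(counts)) || any(counts < 0)) {
    dd_stop("read_jaspar_pwm: malformed counts")
  }
  counts <- counts + pseudocount
  mat <- sweep(counts, 2, colSums(counts), "/")
  new_pwm(mat, background = background)
}

#' Trim a PWM to a column range
#'
#' Retains columns `keep_start..keep_end` (1-based, inclusive), discarding
#' flanking low-information positions; column probabilities are unchanged.
#' Trimming a 21-column matrix to columns 4..18 yields a 15-bp PWM.
#'
#' @param pwm A `pwm`.
#' @param keep_start,keep_end First and last column to keep (1-based).
#' @return A `pwm` of width `keep_end - keep_start + 1`.
#' @export
trim_pwm <- function(pwm, keep_start, keep_end) {
  stopifnot(inherits(pwm, "pwm"))
  if (keep_start < 1L || keep_end > pwm$width || keep_start > keep_end) {
    dd_stop("trim_pwm: column range out of bounds")
  }
  new_pwm(pwm$mat[, keep_start:keep_end, drop = FALSE],
          background = pwm$background)
}

#' Consensus sequence of a PWM
#' @param pwm A `pwm`.
#' @return Character scalar; per-column most probable base (ties: first of
#'   A,C,G,T).
#' @export
pwm_consensus <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  paste(rownames(pwm$mat)[apply(pwm$mat, 2, which.max)], collapse = "")
}

# A=1, C=2, G=3, T=4, N/other = NA
dna_codes <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- utf8ToInt(toupper(seq))
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[x]
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
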