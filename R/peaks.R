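#' Kernel-smoothed accessibility signal
#'
#' Turns a per-base cut profile into a continuous accessibility signal by
#' Gaussian-kernel density smoothing, evaluated at every base. The kernel
#' sums to one, so total signal mass equals the total cut count up to edge
#' loss (< 0.1 % on realistic profiles).
#'
#' @param profile A `cut_profile`.
#' @param bandwidth Gaussian kernel standard deviation in bp (default 60).
#' @return An object of class `signal_track`: per-chromosome numeric
#'   vectors plus the bandwidth.
#' @export
kde_signal <- function(profile, bandwidth = 60) {
  stopifnot(inherits(profile, "cut_profile"), bandwidth > 0)
  half <- as.integer(ceiling(4 * bandwidth))
  kernel <- stats::dnorm(-half:half, sd = bandwidth)
  kernel <- kernel / sum(kernel)
  values <- lapply(profile$cuts, function(v) {
    if (sum(v) == 0L) return(numeric(length(v)))
    n <- length(v)
    # FFT convolution padded to a 2-3-5-smooth length for speed
    m <- stats::nextn(n + length(kernel) - 1L, c(2L, 3L, 5L))
    fv <- stats::fft(c(as.double(v), numeric(m - n)))
    fk <- stats::fft(c(kernel, numeric(m - length(kernel))))
    out <- Re(stats::fft(fv * fk, inverse = TRUE)) / m
    pmax(out[(half + 1L):(half + n)], 0)
  })
  structure(list(values = values, bandwidth = bandwidth,
                 condition = profile$condition),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %d chromosome(s), bandwidth %g bp\n",
              length(x$values), x$bandwidth))
  invisible(x)
}

#' Gamma-tail signal threshold
#'
#' Fits a gamma distribution by maximum likelihood to the positive signal
#' values of a track (zeros dominate the genome and are not
#' gamma-distributed) and returns the upper-tail quantile at `p`: the
#' signal value corresponding to P < `p` under the fitted background
#' distribution. The MLE uses the standard digamma Newton iteration on the
#' shape parameter.
#'
#' @param track A `signal_track`, or a numeric vector of signal values.
#' @param p Upper-tail probability (default 0.05).
#' @return The threshold (numeric scalar). Monotone decreasing in `p`.
#' @export
gamma_threshold <- function(track, p = 0.05) {
  stopifnot(p > 0, p < 1)
  x <- if (inherits(track, "signal_track")) {
    unlist(track$values, use.names = FALSE)
  } else {
    as.numeric(track)
  }
  x <- x[x > 0]
  if (length(x) < 10L) dd_stop("gamma_threshold: too few positive values")
  if (stats::sd(x) < .Machine$double.eps * mean(x)) {
    dd_stop("gamma_threshold: degenerate all-equal signal")
  }
  fit <- gamma_mle(x)
  stats::qgamma(1 - p, shape = fit$shape, rate = fit$rate)
}

# Gamma MLE: moment start for the shape, then Newton steps on
# log(k) - digamma(k) = log(mean) - mean(log x)
gamma_mle <- function(x) {
  s <- log(mean(x)) - mean(log(x))
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:25) {
    step <- (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * k) { k <- k_new; break }
    k <- k_new
  }
  list(shape = k, rate = k / mean(x))
}

#' Call peaks from a signal track
#'
#' Peaks are maximal runs of bases with signal at or above `threshold`;
#' runs separated by fewer than `min_gap` bases are merged (so single
#' nucleosome-depleted regions are not fragmented). Each peak is scored by
#' its maximum signal.
#'
#' @param track A `signal_track`.
#' @param threshold Signal threshold (e.g. from [gamma_threshold()]).
#' @param min_gap Merge peaks separated by fewer than this many bp
#'   (default 50).
#' @return Sorted interval `data.frame` with `score` = max signal; empty
#'   when no base exceeds the threshold.
#' @export
call_peaks <- function(track, threshold, min_gap = 50) {
  stopifnot(inherits(track, "signal_track"), threshold > 0, min_gap >= 0)
  out <- list()
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    r <- rle(v >= threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    ps <- starts[r$values]; pe <- ends[r$values]
    if (!length(ps)) next
    # merge runs separated by < min_gap
    if (length(ps) > 1L) {
      gap <- ps[-1L] - pe[-length(pe)]
      grp <- cumsum(c(0L, as.integer(gap >= min_gap)))
      ps <- tapply(ps, grp, min)
      pe <- tapply(pe, grp, max)
    }
    score <- vapply(seq_along(ps), function(i) {
      max(v[(ps[i] + 1L):pe[i]])
    }, numeric(1))
    out[[chrom]] <- genomic_intervals(chrom, ps, pe, score = score)
  }
  if (!length(out)) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$name <- sprintf("peak_%d", seq_len(nrow(res)))
  res
}

#' Smooth, threshold and call DHS peaks in one step
#'
#' Convenience wrapper: [kde_signal()] then [gamma_threshold()] then
#' [call_peaks()].
#'
#' @param profile A `cut_profile` (typically replicates pooled per
#'   condition).
#' @param bandwidth Kernel bandwidth in bp.
#' @param p Gamma upper-tail probability.
#' @param min_gap Peak merge gap in bp.
#' @return List with `peaks` (interval `data.frame`), `threshold`, and
#'   `track` (the `signal_track`).
#' @export
call_dhs <- function(profile, bandwidth = 60, p = 0.05, min_gap = 50) {
  track <- kde_signal(profile, bandwidth = bandwidth)
  thr <- gamma_threshold(track, p = p)
  list(peaks = call_peaks(track, thr, min_gap = min_gap),
       threshold = thr, track = track)
}

#' Write peaks as BED6 with UCSC-style scores
#'
#' Scores are max signal times 1000, rounded, for browser display.
#'
#' @param peaks Interval `data.frame` with `score`.
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- peaks
  out$score <- round(out$score * 1000)
  write_bed(out, path)
}
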