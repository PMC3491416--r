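#' Derive a reproducible child seed
#'
#' Folds a base seed together with an arbitrary sequence of labels (stage
#' names, condition, replicate index, run index, ...) into a single integer
#' seed below 2^31, so that every stochastic stage of the pipeline can be
#' seeded independently and reproducibly from one user-supplied seed.
#'
#' @param seed Integer base seed.
#' @param ... Labels (coerced to character) identifying the consumer.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  parts <- unlist(lapply(list(...), function(x) {
    utf8ToInt(paste(as.character(x), collapse = ","))
  }))
  h <- as.double(seed) %% 2147483647
  for (v in parts) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

# stop() with a consistent prefix; internal
dd_stop <- function(...) stop(..., call. = FALSE)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
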