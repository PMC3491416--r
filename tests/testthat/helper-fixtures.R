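# Shared fixtures and independent reference implementations used as
# oracles. References are written directly from the rule definitions, in a
# different style from the package code, so they can catch transcription
# errors in the implementation.

# small, fast scenario for module-level tests
small_scenario <- function(seed = 1, ...) {
  build_scenario(L = 2e5, n_dhs = 50, n_increase = 8,
                 sites_per_template = 10, n_genes = 30, n_de = 6,
                 seed = seed, ...)
}

# scenario without motif sites and with sparse planted increases, so a
# random gene rarely has one within the 20-kb association window; this
# isolates the region--gene association signal
assoc_scenario <- function(seed = 1) {
  build_scenario(L = 2e6, n_dhs = 150, n_increase = 10,
                 sites_per_template = 0, n_genes = 80, n_de = 10,
                 seed = seed)
}

# strongly informative 4-bp test PWM with a non-palindromic consensus
# (AACG), so forward and reverse-complement scores differ
tiny_pwm <- function(background = uniform_background()) {
  m <- matrix(0.04, 4, 4)
  m[cbind(c(1, 1, 2, 3), 1:4)] <- 0.88
  new_pwm(m, background = background)
}

random_profile <- function(L = 500, lambda = 0.5, chrom = "chrT",
                           condition = "untreated", replicate = "r1") {
  cut_profile(stats::setNames(list(rpois(L, lambda)), chrom),
              replicate = replicate, condition = condition)
}

# reference tiling: per-base coverage bookkeeping, following the window
# rule as stated (single centered window; n default-stride windows kept if
# each edge discards < edge_frac * len; else n+1 windows exactly covering)
reference_tile <- function(start, end, W = 300L, step = 150L,
                           edge_frac = 0.10) {
  len <- end - start
  if (len <= W) {
    s <- start - floor((W - len) / 2)
    return(cbind(max(s, 0L), max(s, 0L) + W))
  }
  n <- floor((len - W) / step) + 1
  covered <- (n - 1) * step + W
  lost <- len - covered
  lost_left <- floor(lost / 2)
  lost_right <- lost - lost_left
  if (lost_left < edge_frac * len && lost_right < edge_frac * len) {
    s <- start + lost_left + (0:(n - 1)) * step
    return(cbind(s, s + W))
  }
  offs <- floor((0:n) * (len - W) / n)
  offs[n + 1] <- len - W
  s <- start + offs
  cbind(s, s + W)
}

# brute-force pieces of the first-order log-likelihood score
reference_pwm_ll <- function(bases, pwm) {
  sum(vapply(seq_along(bases), function(j) {
    log(max(pwm$mat[bases[j], j], 1e-12))
  }, 0))
}

reference_bg_ll <- function(bases, pwm) {
  bg <- log(pwm$background$stationary[[bases[1]]])
  for (j in seq_along(bases)[-1]) {
    bg <- bg + log(pwm$background$transition[bases[j - 1], bases[j]])
  }
  bg
}

reference_window_score <- function(bases, pwm) {
  reference_pwm_ll(bases, pwm) - reference_bg_ll(bases, pwm)
}

# brute-force scan: per-strand score of every N-free window; the minus
# strand scores the reverse complement against the PWM over the same
# forward-window background term
reference_scan_scores <- function(seq, pwm) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seq, "")[[1]]
  w <- pwm$width
  np <- length(chars) - w + 1
  rows <- lapply(seq_len(np), function(p) {
    win <- chars[p:(p + w - 1)]
    if (any(!win %in% names(comp))) return(NULL)
    rc <- rev(unname(comp[win]))
    bg <- reference_bg_ll(win, pwm)
    data.frame(start = p - 1L,
               fwd = reference_pwm_ll(win, pwm) - bg,
               rev = reference_pwm_ll(rc, pwm) - bg)
  })
  do.call(rbind, rows)
}

# independent optimal center matching: score every permutation built by
# expanding index orderings recursively over a worklist
reference_match_total <- function(cm) {
  k <- nrow(cm)
  best <- -Inf
  stack <- list(integer(0))
  while (length(stack)) {
    head <- stack[[1]]; stack <- stack[-1]
    if (length(head) == k) {
      tot <- sum(cm[cbind(seq_len(k), head)])
      if (tot > best) best <- tot
    } else {
      for (j in setdiff(seq_len(k), head)) {
        stack[[length(stack) + 1]] <- c(head, j)
      }
    }
  }
  best
}

random_sequence <- function(L, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
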