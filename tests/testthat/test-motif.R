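test_that("PWM trimming keeps 1-based inclusive column ranges", {
  m <- matrix(1 / 4, 4, 21)
  m[1, ] <- seq(0.05, 0.25, length.out = 21)
  m <- sweep(m, 2, colSums(m), "/")
  pwm <- new_pwm(m)
  t1 <- trim_pwm(pwm, 4, 18)
  expect_equal(t1$width, 15L)
  expect_equal(t1$mat, pwm$mat[, 4:18], ignore_attr = TRUE)
  expect_equal(trim_pwm(pwm, 1, 21)$mat, pwm$mat)
  expect_equal(trim_pwm(pwm, 7, 7)$width, 1L)
  expect_error(trim_pwm(pwm, 0, 5), "range")
  expect_error(trim_pwm(pwm, 5, 22), "range")
})

test_that("scanning a uniform PWM under its own order-0 background keeps all ties", {
  u <- new_pwm(matrix(0.25, 4, 4))
  seqs <- c(s = random_sequence(300, seed = 2))
  m <- scan_sequence(seqs, u, percentile = 90, background = u$background)
  expect_true(all(abs(m$score) < 1e-12))
  expect_equal(nrow(m), 300 - 4 + 1)  # constant scores: every window kept
})

test_that("scan equals brute-force rescoring of every window", {
  pwm <- tiny_pwm()
  seqs <- c(s = random_sequence(2000, seed = 4))
  bg <- background_from_sequence(seqs[[1]])
  pwm <- new_pwm(pwm$mat, background = bg)
  got <- scan_sequence(seqs, pwm, percentile = 90, background = bg)
  ref <- reference_scan_scores(seqs[[1]], pwm)
  thr <- quantile(c(ref$fwd, ref$rev), 0.9, names = FALSE)
  keep <- ref$fwd >= thr | ref$rev >= thr
  expect_equal(got$start, ref$start[keep])
  expect_equal(got$score, pmax(ref$fwd, ref$rev)[keep], tolerance = 1e-9)
  expect_equal(got$strand, ifelse(ref$fwd[keep] >= ref$rev[keep], "+", "-"))
})

test_that("scanning is strand-symmetric", {
  pwm <- tiny_pwm()
  seqs <- c(s = random_sequence(3000, seed = 6))
  fwd <- scan_sequence(seqs, pwm, percentile = 95)
  rc <- c(s = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seqs[[1]]))))
  rev <- scan_sequence(rc, pwm, percentile = 95)
  expect_equal(sort(fwd$score), sort(rev$score), tolerance = 1e-9)
  L <- nchar(seqs[[1]]); w <- pwm$width
  expect_setequal(L - w - fwd$start, rev$start)
  m <- merge(data.frame(start = L - w - fwd$start, strand_f = fwd$strand),
             data.frame(start = rev$start, strand_r = rev$strand))
  swapped <- m$strand_f != m$strand_r
  expect_true(mean(swapped) > 0.9)  # ties may keep '+' on both
})

test_that("windows containing N are skipped", {
  pwm <- tiny_pwm()
  s <- random_sequence(200, seed = 9)
  substr(s, 100, 100) <- "N"
  got <- scan_sequence(c(s = s), pwm, percentile = 50)
  expect_false(any(got$start %in% 96:99))  # windows covering position 99 (0-based)
})

test_that("the consensus window scores at least as high as any other string", {
  pwm <- new_pwm(tiny_pwm()$mat, uniform_background())
  strings <- expand.grid(rep(list(c("A", "C", "G", "T")), 4),
                         stringsAsFactors = FALSE)
  scores <- apply(strings, 1, function(b) reference_window_score(b, pwm))
  cons <- reference_window_score(strsplit(pwm_consensus(pwm), "")[[1]], pwm)
  expect_equal(max(scores), cons)
})

test_that("relative enrichment compares match frequencies between region sets", {
  matches <- genomic_intervals("c", seq(0, 700, 100)[1:8] * 10 + 2,
                               seq(0, 700, 100)[1:8] * 10 + 6)
  set_a <- genomic_intervals("c", seq(0, 900, 100) * 10,
                             seq(0, 900, 100) * 10 + 50)  # 8/10 with a match
  set_b <- genomic_intervals("c", c(0, 100, 5000, 5100, 5200, 5300, 5400,
                                    5500, 5600, 5700) * 10,
                             c(0, 100, 5000, 5100, 5200, 5300, 5400,
                               5500, 5600, 5700) * 10 + 50)  # 2/10
  re <- relative_enrichment(matches, set_a, set_b)
  expect_equal(re$frac_a, 0.8)
  expect_equal(re$frac_b, 0.2)
  expect_equal(re$score, 4.0)

  expect_equal(relative_enrichment(matches, set_a, set_a)$score, 1.0)
  empty_b <- genomic_intervals("c", 99000, 99100)
  expect_error(relative_enrichment(matches, set_a, empty_b), "undefined|no B")
})

test_that("planted motif sites are recovered by scanning at the 90th percentile", {
  sc <- small_scenario(seed = 13)
  pwm <- read_jaspar_pwm(system.file("extdata", "ar_like_synthetic.jaspar",
                                     package = "deltadnase"), pseudocount = 1)
  seqs <- simulate_sequence(sc, pwm)
  matches <- scan_sequence(seqs, pwm, percentile = 90,
                           mask = sc$dhs[, c("chrom", "start", "end")])
  truth <- sc$motif_sites
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(matches$start == truth$start[i])
  }, TRUE)
  expect_gte(mean(hit), 0.95)
})

test_that("best-match selection keeps one top match per region", {
  matches <- genomic_intervals("c", c(10, 40, 210, 400), c(25, 55, 225, 415),
                               score = c(5, 9, 3, 7))
  regions <- genomic_intervals("c", c(0, 200), c(100, 300))
  best <- best_match_per_region(matches, regions)
  expect_equal(best$start, c(40L, 210L))
  dd <- dedupe_matches(genomic_intervals("c", c(10, 12, 100), c(25, 27, 115),
                                         score = c(2, 8, 1)))
  expect_equal(dd$start, c(12L, 100L))
})
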