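test_that("scenarios are deterministic and structurally valid", {
  a <- small_scenario(seed = 5)
  b <- small_scenario(seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, small_scenario(seed = 6)))

  expect_equal(nrow(a$dhs), 50L)
  expect_equal(sum(a$delta$direction == "increase"), 8L)
  expect_equal(nrow(a$motif_sites), 30L)
  expect_equal(as.vector(table(a$motif_sites$template)), rep(10L, 3))
  # planted regions and motif sites sit inside DHS
  expect_equal(overlap_fraction(a$delta, a$dhs)$frac_a, 1)
  expect_equal(overlap_fraction(a$motif_sites[, c("chrom", "start", "end")],
                                a$dhs)$frac_a, 1)
})

test_that("a zero-DHS scenario is background only", {
  sc <- build_scenario(L = 5e4, n_dhs = 0, n_genes = 0, seed = 2)
  expect_equal(nrow(sc$dhs), 0L)
  expect_equal(nrow(sc$delta), 0L)
  expect_equal(nrow(sc$motif_sites), 0L)
  r <- scenario_rates(sc, "induced")
  expect_true(all(r == sc$lambda_bg))
})

test_that("cut simulation is reproducible and Poisson totals are calibrated", {
  sc <- build_scenario(L = 1e6, n_dhs = 0, n_genes = 0, lambda_bg = 0.01,
                       phi = 0, seed = 3)
  p1 <- simulate_cuts(sc, "untreated", 1)
  p2 <- simulate_cuts(sc, "untreated", 1)
  expect_identical(p1$cuts, p2$cuts)
  expect_false(identical(p1$cuts, simulate_cuts(sc, "untreated", 2)$cuts))
  # total ~ Poisson(10^4): within +-3*sqrt(10^4) virtually always
  expect_lt(abs(total_cuts(p1) - 1e4), 3 * sqrt(1e4))
  expect_error(simulate_cuts(sc, "warmed", 1))
})

test_that("planted fold-change regions show the requested mean ratio", {
  sc <- small_scenario(seed = 11)
  reg <- sc$delta[1, , drop = FALSE]
  span <- (reg$start + 1):reg$end
  # ratio of mean counts (a mean of per-pair ratios would be biased
  # upward by the replicate-level region variability in the denominator)
  sums <- vapply(1:60, function(r) {
    i <- simulate_cuts(sc, "induced", sample.int(1e6, 1))
    u <- simulate_cuts(sc, "untreated", sample.int(1e6, 1))
    c(sum(i$cuts[[1]][span]), sum(u$cuts[[1]][span]))
  }, numeric(2))
  expect_equal(mean(sums[1, ]) / mean(sums[2, ]), sc$fold, tolerance = 0.1)
})

test_that("footprint templates have the documented shapes and symmetry", {
  tm <- footprint_templates()
  expect_true(all(vapply(tm, length, 0L) == 31L))
  expect_true(all(unlist(tm) >= 0 & unlist(tm) <= 1))
  expect_equal(tm$left_half, rev(tm$right_half))
  expect_equal(tm$left_half[1:14], rep(0.15, 14))
  expect_equal(tm$left_half[15:31], rep(1, 17))
  expect_equal(tm$full_dimer[15:17], rep(1, 3))
  expect_equal(tm$full_dimer[c(1:14, 18:31)], rep(0.15, 28))
})

test_that("an all-zero protection template silences cuts at the site", {
  sc <- small_scenario(seed = 4)
  sc$templates <- lapply(sc$templates, function(t) t * 0)
  for (r in 1:3) {
    cuts <- simulate_cuts(sc, "induced", r)$cuts[[1]]
    for (i in seq_len(nrow(sc$motif_sites))) {
      s <- sc$motif_sites[i, ]
      center <- s$start + (s$end - s$start) %/% 2
      expect_true(all(cuts[(center - 14):(center + 16)] == 0))
    }
  }
})

test_that("simulated sequence carries the planted motif instances", {
  # deterministic consensus PWM: planted bases are forced
  m <- matrix(1e-12, 4, 15); m[cbind(rep(1, 15), 1:15)] <- 1
  m <- sweep(m, 2, colSums(m), "/")
  pwm <- new_pwm(m)
  sc <- small_scenario(seed = 9)
  seqs <- simulate_sequence(sc, pwm)
  chars <- strsplit(seqs[[1]], "")[[1]]
  for (i in seq_len(nrow(sc$motif_sites))) {
    s <- sc$motif_sites[i, ]
    inst <- paste(chars[(s$start + 1):s$end], collapse = "")
    expected <- if (s$strand == "+") strrep("A", 15) else strrep("T", 15)
    expect_equal(inst, expected)
  }
})

test_that("expression counts respect DE structure", {
  sc <- small_scenario(seed = 21)
  cm <- simulate_expression(sc)
  expect_identical(cm$counts, simulate_expression(sc)$counts)
  g <- sc$genes$genes
  ind <- cm$condition == "induced"
  # Monte Carlo over replicate scenarios: DE mean ratio -> de_fold
  ratios <- vapply(which(g$de), function(i) {
    mean(cm$counts[i, ind]) / max(mean(cm$counts[i, !ind]), 1e-9)
  }, 0)
  expect_equal(mean(ratios), sc$de_fold, tolerance = 0.35)
  nde <- vapply(which(!g$de), function(i) {
    mean(cm$counts[i, ind]) / max(mean(cm$counts[i, !ind]), 1e-9)
  }, 0)
  expect_equal(mean(nde), 1, tolerance = 0.15)
  # zero-expression gene gives all-zero counts
  sc$genes$genes$base_mean[1] <- 0
  expect_true(all(simulate_expression(sc)$counts[1, ] == 0))
})

test_that("marginal count distribution matches the declared NB law", {
  sc <- build_scenario(L = 1e5, n_dhs = 0, n_genes = 0, lambda_bg = 2,
                       phi = 0.2, seed = 8)
  x <- simulate_cuts(sc, "untreated", 1)$cuts[[1]]
  expect_equal(mean(x), 2, tolerance = 0.02)
  expect_equal(var(x), 2 + 0.2 * 4, tolerance = 0.05)
  probs <- dnbinom(0:14, size = 1 / 0.2, mu = 2)
  obs <- tabulate(pmin(x, 14) + 1L, 15L)
  expected <- length(x) * c(probs[1:14], 1 - sum(probs[1:14]))
  chi <- suppressWarnings(chisq.test(obs, p = expected / sum(expected)))
  expect_gt(chi$p.value, 0.001)
})
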