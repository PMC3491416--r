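test_that("union of region sets merges overlaps and respects inclusion-exclusion", {
  a <- genomic_intervals("c", 0, 100)
  b <- genomic_intervals("c", 50, 150)
  u <- union_regions(a, b)
  expect_equal(u[, c("start", "end")], data.frame(start = 0L, end = 150L))

  d1 <- genomic_intervals("c", c(0, 500), c(100, 600))
  d2 <- genomic_intervals("c", 300, 400)
  u2 <- union_regions(d1, d2)
  expect_equal(u2$start, c(0L, 300L, 500L))

  set.seed(12)
  cov <- function(df) {
    x <- logical(2000)
    for (j in seq_len(nrow(df))) x[(df$start[j] + 1):df$end[j]] <- TRUE
    x
  }
  for (i in 1:25) {
    s <- sort(sample(0:500, 5)) * 3
    a <- genomic_intervals("c", s, s + sample(5:80, 5))
    s2 <- sort(sample(0:500, 5)) * 3
    b <- genomic_intervals("c", s2, s2 + sample(5:80, 5))
    u <- union_regions(a, b)
    expect_equal(sum(u$end - u$start), sum(cov(a) | cov(b)))
  }
})

test_that("tiling matches the brute-force reference on specific cases", {
  # short region: one centered 300-bp window
  w <- tile_region(genomic_intervals("c", 1000, 1200))
  expect_equal(w[, c("start", "end")], data.frame(start = 950L, end = 1250L))
  # exactly window-sized region: itself
  w2 <- tile_region(genomic_intervals("c", 1000, 1300))
  expect_equal(w2[, c("start", "end")], data.frame(start = 1000L, end = 1300L))
  # len 750: default stride accepted, full centered coverage
  w3 <- tile_region(genomic_intervals("c", 0, 750))
  ref <- reference_tile(0, 750)
  expect_equal(as.matrix(w3[, c("start", "end")]), ref, ignore_attr = TRUE)
  expect_equal(nrow(w3), 4L)
  expect_true(all(w3$end - w3$start == 300L))
})

test_that("window counting equals brute-force per-bp summation", {
  set.seed(33)
  prof <- random_profile(L = 3000, lambda = 1)
  windows <- genomic_intervals("chrT", st <- sample(0:2600, 200, TRUE),
                               st + sample(10:300, 200, TRUE))
  cm <- count_and_filter(windows, list(prof), min_sum = 0)
  v <- prof$cuts$chrT
  brute <- vapply(seq_len(nrow(windows)), function(i) {
    sum(v[(windows$start[i] + 1):windows$end[i]])
  }, 0)
  expect_equal(unname(cm$counts[, 1]), brute)
})

test_that("the minimum-sum filter is strict", {
  prof1 <- cut_profile(list(c = c(1L, 1L, 1L, 1L, 0L, 5L)), "r1", "untreated")
  prof2 <- cut_profile(list(c = integer(6)), "r2", "induced")
  w <- genomic_intervals("c", c(0, 5), c(5, 6))
  cm <- count_and_filter(w, list(prof1, prof2), min_sum = 5)
  # row sums: (4, 5): 4 eliminated, exactly 5 retained
  expect_equal(nrow(cm$counts), 1L)
  expect_equal(cm$features$start, 5L)
})

test_that("the exact NB test has the right limits and matches edgeR", {
  # identical counts, equal library sizes: p = 1 everywhere
  m <- matrix(rep(c(5L, 9L, 14L), each = 6), nrow = 3, byrow = TRUE)
  cm <- count_matrix(m, condition = rep(c("untreated", "induced"), 3),
                     lib_sizes = rep(1000, 6))
  res <- nb_exact_test(cm, dispersion = 0.1)
  expect_true(all(res$table$pvalue == 1))

  # Poisson limit: conditional test reduces to the exact binomial test
  for (tt in list(c(3L, 12L), c(20L, 9L), c(0L, 7L))) {
    mine <- deltadnase:::nb_exact_pvalue(tt[1], tt[2], 3, 3, phi = 0)
    bin <- binom.test(tt[1], sum(tt), p = 0.5)$p.value
    expect_equal(mine, bin, tolerance = 1e-5)
  }

  # dual route: independent reference implementation of the cited method
  set.seed(7)
  m2 <- matrix(rnbinom(500 * 6, size = 1 / 0.15, mu = 40), 500, 6)
  grp <- rep(c("untreated", "induced"), each = 3)
  mine <- nb_exact_test(count_matrix(m2, condition = grp))
  d <- edgeR::DGEList(counts = m2,
                      group = factor(grp, levels = c("untreated", "induced")))
  d <- edgeR::calcNormFactors(d)
  d <- edgeR::estimateCommonDisp(d)
  et <- edgeR::exactTest(d)
  expect_equal(mine$dispersion, d$common.dispersion, tolerance = 0.02)
  expect_gt(cor(log(mine$table$pvalue), log(et$table$PValue)), 0.995)
  expect_lt(median(abs(log10(mine$table$pvalue / et$table$PValue))), 0.05)

  expect_error(nb_exact_test(count_matrix(m2, condition = grp,
                                          lib_sizes = c(0, 0, 0, 1, 1, 1) * 100)),
               "all-zero")
})

test_that("significant windows merge by direction with book-ended neighbors", {
  tab <- data.frame(
    chrom = "c",
    start = c(0L, 150L, 450L, 600L, 2000L),
    end = c(300L, 450L, 750L, 900L, 2300L),
    logFC = c(2, 2, -2, 2, 2),
    pvalue = c(1e-6, 1e-4, 1e-6, 1e-6, 0.2)
  )
  tab$fdr <- p.adjust(tab$pvalue, "BH")
  res <- structure(list(table = tab, dispersion = 0.1), class = "diff_result")
  sets <- classify_and_merge(res)
  # overlapping increase windows merge; book-ended window 600-900 joins the
  # decrease's neighbor only if same direction - here it stays separate
  expect_equal(nrow(sets$strict_increase), 2L)
  expect_equal(sets$strict_increase$start, c(0L, 600L))
  expect_equal(sets$strict_increase$end, c(450L, 900L))
  expect_equal(nrow(sets$strict_decrease), 1L)
  # region p is the minimum window p
  expect_equal(sets$strict_increase$pvalue[1], 1e-6)
  # the non-significant window appears nowhere
  expect_false(any(sets$loose_increase$start == 2000))
})

test_that("strict region sets are nested in loose sets on random data", {
  set.seed(41)
  for (i in 1:20) {
    n <- 80
    mu <- runif(n, 5, 60)
    shift <- ifelse(runif(n) < 0.2, sample(c(0.3, 3), n, TRUE), 1)
    m <- cbind(matrix(rnbinom(n * 3, size = 8, mu = mu), n),
               matrix(rnbinom(n * 3, size = 8, mu = mu * shift), n))
    st <- seq(0, by = 400, length.out = n)
    cm <- count_matrix(m, condition = rep(c("untreated", "induced"), each = 3),
                       features = genomic_intervals("c", st, st + 300))
    sets <- classify_and_merge(nb_exact_test(cm))
    for (dir in c("increase", "decrease")) {
      strict <- sets[[paste0("strict_", dir)]]
      loose <- sets[[paste0("loose_", dir)]]
      if (nrow(strict)) {
        expect_equal(overlap_fraction(strict, loose)$frac_a, 1)
      }
    }
  }
})

test_that("normalized differential scores are centered and rank planted regions", {
  sc <- small_scenario(seed = 17)
  profs <- simulate_all_cuts(sc)
  union <- sc$dhs[, c("chrom", "start", "end", "name")]
  sc_scores <- normalized_differential_score(union, profs)
  expect_equal(mean(sc_scores), 0, tolerance = 1e-12)

  # identical profiles in both conditions: all scores zero
  same <- c(profs[1:2], lapply(profs[1:2], function(p) {
    p$condition <- "induced"; p
  }))
  expect_equal(normalized_differential_score(union, same), rep(0, nrow(union)))

  # planted f=3 regions rank at the top
  planted <- overlap_fraction(union, sc$delta)$frac_a * nrow(union)
  top <- union[rank(-sc_scores) <= planted, ]
  expect_gte(overlap_fraction(sc$delta, top)$frac_a, 0.8)
})
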