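test_that("footprint rows are centered, strand-oriented cut vectors", {
  v <- integer(200)
  p <- cut_profile(list(c = v))
  site <- genomic_intervals("c", 92, 107, strand = "+")  # center 99
  fm0 <- footprint_matrix(p, site)
  expect_equal(dim(fm0), c(1L, 31L))
  expect_true(all(fm0 == 0))

  v[100] <- 1L  # 0-based position 99 = the center
  p1 <- cut_profile(list(c = v))
  fm1 <- footprint_matrix(p1, site)
  expect_equal(unname(unclass(fm1)[1, ]), c(rep(0, 15), 1, rep(0, 15)))

  # '-' strand row equals the reversed '+' extraction
  set.seed(14)
  v2 <- rpois(200, 1)
  p2 <- cut_profile(list(c = v2))
  plus <- footprint_matrix(p2, site)
  minus_site <- site; minus_site$strand <- "-"
  minus <- footprint_matrix(p2, minus_site)
  expect_equal(unclass(minus)[1, ], rev(unclass(plus)[1, ]), ignore_attr = TRUE)

  # sites hanging over the chromosome edge are skipped with a warning
  edge <- genomic_intervals("c", c(0, 92), c(15, 107))
  expect_warning(fme <- footprint_matrix(p2, edge), "skipped")
  expect_equal(nrow(fme), 1L)
  expect_equal(attr(fme, "n_skipped"), 1L)
})

test_that("aggregate profiles sum site windows and conserve cuts", {
  set.seed(15)
  v <- rpois(2000, 0.8)
  p <- cut_profile(list(c = v))
  sites <- genomic_intervals("c", c(200, 600, 1200), c(215, 615, 1215),
                             strand = c("+", "+", "-"))
  agg <- aggregate_profile(p, sites, flank = 100)
  expect_length(agg, 15 + 200)
  total <- sum(vapply(seq_len(3), function(i) {
    sum(v[(sites$start[i] - 100 + 1):(sites$end[i] + 100)])
  }, 0))
  expect_equal(sum(agg), total)

  one <- aggregate_profile(p, sites[1, ], flank = 50)
  expect_equal(one, v[(200 - 50 + 1):(215 + 50)])
})

test_that("optimal center matching agrees with independent enumeration", {
  set.seed(16)
  for (k in 2:4) {
    c1 <- matrix(rnorm(k * 31), k)
    c2 <- matrix(rnorm(k * 31), k)
    got <- match_centers(c1, c2)
    cm <- matrix(0, k, k)
    for (i in 1:k) for (j in 1:k) cm[i, j] <- cor(c1[i, ], c2[j, ])
    expect_equal(sum(got), reference_match_total(cm), tolerance = 1e-12)
  }
  # zero-variance centers correlate 0 by convention
  cz <- matrix(1, 2, 31)
  cn <- matrix(rnorm(62), 2)
  expect_equal(match_centers(cz, cn), c(0, 0))
})

test_that("stability separates planted template structure from noise", {
  tm <- footprint_templates()
  set.seed(18)
  planted <- do.call(rbind, lapply(rep(names(tm), each = 60), function(nm) {
    rpois(31, 30 / 31 * 3 * tm[[nm]] / mean(tm[[nm]]))
  }))
  st <- kmeans_stability(planted, k = 3, runs = 30, seed = 2,
                         row_normalize = TRUE)
  expect_gt(st$median, 0.99)
  cent <- consensus_centers(st)
  best <- vapply(1:3, function(i) {
    max(vapply(tm, function(t) cor(cent[i, ], t), 0))
  }, 0)
  expect_true(all(best > 0.9))

  noise <- matrix(rpois(180 * 31, 3), 180)
  stn <- kmeans_stability(noise, k = 3, runs = 30, seed = 2,
                          row_normalize = TRUE)
  expect_lt(stn$median, 0.8)
  expect_lt(stn$median, st$median)

  expect_error(kmeans_stability(noise[1:2, ], k = 3, runs = 5, seed = 1),
               "exceeds")
})

test_that("two identical deterministic runs give all correlations 1", {
  tm <- footprint_templates()
  clean <- do.call(rbind, lapply(rep(names(tm), each = 20), function(nm) {
    round(100 * tm[[nm]])
  }))
  st <- kmeans_stability(clean, k = 3, runs = 2, seed = 7)
  expect_equal(st$correlations, rep(1, 3), tolerance = 1e-12)
})

test_that("stability comparison is symmetric and handles identical inputs", {
  set.seed(20)
  m1 <- rbind(matrix(rpois(40 * 31, 20), 40),
              matrix(rpois(40 * 31, c(3, 20)), 40))
  a <- kmeans_stability(m1, k = 2, runs = 15, seed = 1)
  cmp_same <- compare_stability(a, a)
  expect_gt(cmp_same$p_value, 0.9)
  expect_equal(cmp_same$higher, "tie")

  b <- kmeans_stability(matrix(rpois(80 * 31, 20), 80), k = 2, runs = 15,
                        seed = 1)
  ab <- compare_stability(a, b, "first", "second")
  ba <- compare_stability(b, a, "second", "first")
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$higher, ba$higher)
})

test_that("k selection is deterministic and flags the planted cluster count", {
  tm <- footprint_templates()
  set.seed(22)
  planted <- do.call(rbind, lapply(rep(names(tm), each = 50), function(nm) {
    rpois(31, 30 / 31 * 3 * tm[[nm]] / mean(tm[[nm]]))
  }))
  s1 <- select_k(planted, k_range = 2:4, runs = 20, seed = 5,
                 row_normalize = TRUE)
  s2 <- select_k(planted, k_range = 2:4, runs = 20, seed = 5,
                 row_normalize = TRUE)
  expect_identical(s1, s2)
  expect_equal(s1$recommended_k, 3L)
  expect_equal(nrow(s1$summary), 3L)
})
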