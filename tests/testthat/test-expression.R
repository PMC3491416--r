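make_gene_fixture <- function() {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "c",
                      strand = c("+", "-"), start = c(0L, 2000L),
                      end = c(1000L, 3000L), tss = c(0L, 2999L))
  exons <- data.frame(gene_id = c("gA", "gA", "gB"), chrom = "c",
                      start = c(0L, 600L, 2000L), end = c(200L, 1000L, 3000L))
  utr3 <- data.frame(gene_id = c("gA", "gB"), chrom = "c",
                     start = c(900L, 2000L), end = c(1000L, 2100L))
  gene_models(genes, exons, utr3)
}

test_that("tags are counted by their 5' base within exons", {
  gm <- make_gene_fixture()
  tags <- genomic_intervals("c",
                            start = c(10, 300, 650, 2500, 2951, 950, 2020),
                            end = c(45, 335, 685, 2535, 2986, 985, 2055),
                            strand = c("+", "+", "+", "-", "-", "+", "-"))
  # intron tag at 300 not counted; '-' tag 5' base = end-1
  counts <- gene_counts(gm, tags)
  expect_equal(unname(counts["gA"]), 3)
  expect_equal(unname(counts["gB"]), 3)

  # excluding 3'UTR drops the 5' bases at 950 (gA UTR) and 2054 (gB UTR)
  counts2 <- gene_counts(gm, tags, exclude_utr3 = TRUE)
  expect_equal(unname(counts2["gA"]), 2)
  expect_equal(unname(counts2["gB"]), 2)

  # brute-force containment oracle on random fixtures
  set.seed(3)
  rt <- genomic_intervals("c", s <- sample(0:2990, 300, TRUE), s + 10,
                          strand = sample(c("+", "-"), 300, TRUE))
  pos <- ifelse(rt$strand == "-", rt$end - 1, rt$start)
  brute <- vapply(c("gA", "gB"), function(g) {
    e <- gm$exons[gm$exons$gene_id == g, ]
    sum(vapply(pos, function(p) any(p >= e$start & p < e$end), TRUE))
  }, 0)
  expect_equal(gene_counts(gm, rt), brute)
})

test_that("RPKM follows its formula and scaling laws", {
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(100, 1000, 1e6), 100)
  expect_equal(rpkm(100, 1000, 2e6), 50)
  expect_error(rpkm(10, 0, 1e6), "length")

  gm <- make_gene_fixture()
  # gA: exonic 600 minus 100 bp UTR overlap; gB: 1000 minus 100
  expect_equal(unname(exonic_length(gm)), c(500, 900))
  expect_equal(unname(exonic_length(gm, exclude_utr3 = FALSE)), c(600, 1000))
})

test_that("DE calling recovers planted genes and splits by sign", {
  set.seed(19)
  n <- 200
  de_idx <- 1:40
  mu <- rep(100, n)
  m_u <- matrix(rnbinom(n * 3, size = 10, mu = mu), n)
  mu_i <- mu; mu_i[de_idx] <- mu[de_idx] * 4
  m_i <- matrix(rnbinom(n * 3, size = 10, mu = mu_i), n)
  cm <- count_matrix(cbind(m_u, m_i),
                     condition = rep(c("untreated", "induced"), each = 3),
                     features = data.frame(gene_id = sprintf("g%03d", 1:n)))
  de <- de_genes(cm)
  expect_gte(length(intersect(de$up, sprintf("g%03d", de_idx))) / 40, 0.9)
  expect_equal(length(intersect(de$up, de$down)), 0L)
  # detected direction matches the planted sign
  expect_true(all(de$up %in% sprintf("g%03d", de_idx)) ||
                length(setdiff(de$up, sprintf("g%03d", de_idx))) <= 2)

  # all-null matrix: about zero DE at FDR 0.05
  m0 <- matrix(rnbinom(n * 6, size = 10, mu = 50), n)
  cm0 <- count_matrix(m0, condition = rep(c("untreated", "induced"), each = 3),
                      features = data.frame(gene_id = sprintf("g%03d", 1:n)))
  de0 <- de_genes(cm0)
  expect_lte(length(de0$up) + length(de0$down), 3L)
})

test_that("gene-level DE and window-level testing share one code path", {
  set.seed(23)
  m <- matrix(rnbinom(100 * 6, size = 10, mu = 30), 100)
  cm <- count_matrix(m, condition = rep(c("untreated", "induced"), each = 3),
                     features = data.frame(gene_id = sprintf("g%d", 1:100)))
  expect_identical(de_genes(cm)$result$table$pvalue,
                   nb_exact_test(cm)$table$pvalue)
})
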