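assoc_gene_fixture <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "c", strand = c("+", "-"),
    start = c(10000L, 40000L), end = c(16000L, 46000L),
    tss = c(10000L, 45999L))
  exons <- data.frame(gene_id = c("gA", "gA", "gB", "gB"), chrom = "c",
                      start = c(10000L, 14000L, 40000L, 44000L),
                      end = c(11000L, 16000L, 42000L, 46000L))
  gene_models(genes, exons)
}

test_that("regions are annotated by midpoint with fixed precedence", {
  gm <- assoc_gene_fixture()
  regions <- genomic_intervals("c",
    start = c(8900, 10400, 12500, 46300, 70000, 13100),
    end = c(9100, 10600, 12700, 46500, 70200, 13300))
  ann <- annotate_regions(regions, gm, promoter = 2000)
  expect_equal(as.character(ann$category),
               c("promoter",           # 1 kb upstream of gA TSS
                 "first_exon_intron",  # inside gA first exon
                 "first_exon_intron",  # inside gA first intron
                 "promoter",           # upstream of gB (minus strand)
                 "intergenic",
                 "first_exon_intron")) # gA intron (between exon1 and 2)
  expect_equal(sum(ann$fractions), 1, tolerance = 1e-9)
  expect_equal(sum(ann$counts), nrow(regions))

  set.seed(5)
  rr <- genomic_intervals("c", s <- sample(0:80000, 200, TRUE), s + 150)
  expect_equal(sum(annotate_regions(rr, gm)$fractions), 1, tolerance = 1e-9)
})

test_that("nearest gene uses midpoint-to-TSS distance with deterministic ties", {
  gm <- assoc_gene_fixture()
  r0 <- genomic_intervals("c", 9950, 10050)  # midpoint exactly at gA TSS
  n0 <- nearest_gene(r0, gm)
  expect_equal(n0$gene_id, "gA")
  expect_equal(n0$distance, 0)

  # exact tie: TSS at 20000 and 36000, region midpoint 28000
  gm2 <- gm
  gm2$genes$tss <- c(20000L, 36000L)
  ntie <- nearest_gene(genomic_intervals("c", 27950, 28050), gm2)
  expect_equal(ntie$gene_id, "gA")  # lexicographically smaller id

  expect_error(nearest_gene(genomic_intervals("chrZ", 0, 10), gm), "chrZ")

  # brute-force all-pairs minimum on random fixtures
  set.seed(8)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "c",
                      strand = "+", start = s <- sort(sample(0:1e5, 20)),
                      end = s + 500L, tss = s)
  gmr <- gene_models(genes, data.frame(gene_id = genes$gene_id, chrom = "c",
                                       start = genes$start, end = genes$end))
  regions <- genomic_intervals("c", q <- sample(0:1e5, 50), q + 100)
  got <- nearest_gene(regions, gmr)
  mids <- (regions$start + regions$end) %/% 2
  for (i in seq_len(50)) {
    expect_equal(got$distance[i], min(abs(mids[i] - genes$tss)))
  }
})

test_that("forward permutation test has exact trivial cases and +1 correction", {
  universe <- sprintf("g%03d", 1:100)
  rg <- universe[1:30]
  pr <- permutation_enrichment(rg, de_set = universe, universe = universe,
                               N = 500, seed = 1)
  expect_equal(pr$observed, 30)
  expect_equal(pr$p_enrich, 1)  # every draw equals the whole universe
  expect_gt(pr$p_deplete, 0)

  pr2 <- permutation_enrichment(rg, universe[31:60], universe, N = 200, seed = 2)
  expect_gt(pr2$p_enrich, 0)    # never exactly zero
  expect_equal(length(pr2$null), 200L)
  expect_error(permutation_enrichment(rg, c("zz"), universe, N = 10, seed = 1),
               "universe")
})

test_that("small-universe permutation null matches the hypergeometric law", {
  universe <- sprintf("g%02d", 1:20)
  rg <- universe[1:8]
  pr <- permutation_enrichment(rg, universe[9:13], universe, N = 20000,
                               seed = 3)
  k <- 0:5
  expected <- dhyper(k, 8, 12, 5) * 20000
  obs <- tabulate(pr$null + 1L, 6L)
  chi <- suppressWarnings(chisq.test(obs, p = expected / sum(expected)))
  expect_gt(chi$p.value, 0.01)
})

test_that("reverse association counts genes with regions in the flanking window", {
  gm <- assoc_gene_fixture()
  inside <- genomic_intervals("c", 12000, 12200)     # inside gA span
  near <- genomic_intervals("c", 56000, 56200)       # 10 kb beyond gB end
  far <- genomic_intervals("c", 90000, 90100)

  r1 <- reverse_association("gA", inside, gm, window = 0, N = 50, seed = 1)
  expect_equal(r1$observed, 1)  # containment still matches at window 0

  r2 <- reverse_association(c("gA", "gB"), near, gm, window = 20000,
                            N = 50, seed = 1)
  expect_equal(unname(r2$has_region), c(FALSE, TRUE))
  expect_equal(r2$observed, 1)

  r3 <- reverse_association("gA", far[0, ], gm, N = 50, seed = 1)
  expect_equal(r3$observed, 0)
  expect_equal(r3$p_enrich, 1)
})

test_that("both directions are significant when DE genes sit near planted increases", {
  sc <- assoc_scenario(seed = 2)
  gm <- sc$genes
  regions <- sc$delta[, c("chrom", "start", "end", "name")]
  de <- gm$genes$gene_id[gm$genes$de]
  universe <- gm$genes$gene_id
  ng <- nearest_gene(regions, gm)
  fwd <- permutation_enrichment(unique(ng$gene_id), de, universe,
                                N = 5000, seed = 9)
  expect_lt(fwd$p_enrich, 0.01)
  rev <- reverse_association(de, regions, gm, window = 20000, N = 1000,
                             seed = 9)
  expect_lt(rev$p_enrich, 0.01)
})
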