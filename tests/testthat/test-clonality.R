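test_that("SNP calling applies the MAF threshold inclusively", {
  mk <- function(a, c) counts_fixture(matrix(c(a, c, 0L, 0L), nrow = 1),
                                      target_depth = 50L)
  expect_identical(nrow(call_snps(mk(45L, 5L))), 1L)   # MAF 0.10 inclusive
  expect_identical(nrow(call_snps(mk(46L, 4L))), 0L)   # 0.08
  expect_identical(nrow(call_snps(mk(50L, 0L))), 0L)   # monomorphic
  snp <- call_snps(mk(45L, 5L))
  expect_identical(snp$major_allele, "A")
  expect_identical(snp$minor_allele, "C")
  expect_equal(snp$maf, 0.1)
  expect_identical(snp$minor_count, 5L)
})

test_that("SNP calling refuses non-uniform (non-downsampled) input", {
  counts <- counts_fixture(matrix(c(45L, 5L, 0L, 0L), nrow = 1))
  expect_error(call_snps(counts), "downsample")
  uneven <- counts_fixture(rbind(c(45L, 5L, 0L, 0L), c(30L, 0L, 0L, 0L)),
                           ref = "AA", target_depth = 50L)
  expect_error(call_snps(uneven), "uniform")
})

test_that("SNP density is per kb of covered sites", {
  mat <- matrix(0L, nrow = 20000, ncol = 4)
  mat[, 1] <- 50L
  counts <- counts_fixture(mat, ref = strrep("A", 20000),
                           target_depth = 50L)
  snps <- call_snps(counts)[0, ]
  snps5 <- do.call(rbind, rep(list(
    data.frame(target_id = "t", pos = 0L, ref_allele = "A",
               major_allele = "A", minor_allele = "C", minor_count = 5L,
               depth_used = 50L, maf = 0.1, degeneracy_class = NA,
               gene_id = NA)), 5))
  d <- snp_density(snps5, counts)
  expect_equal(d$density, 0.25)
  expect_equal(snp_density(snps, counts)$density, 0)

  empty <- counts_fixture(matrix(0L, nrow = 10, ncol = 4),
                          ref = strrep("A", 10), target_depth = 50L)
  expect_error(snp_density(snps, empty), "covered")
})

test_that("exact rank-sum p-values come from full enumeration", {
  r <- rank_sum_one_sided(c(4, 5, 6), c(1, 2, 3))
  expect_identical(r$method, "exact")
  expect_equal(r$p_value, 0.05) # 1 / choose(6, 3)
  expect_equal(rank_sum_one_sided(c(1, 2, 3), c(4, 5, 6))$p_value, 1.0)
  expect_equal(rank_sum_one_sided(2, 1)$p_value, 0.5)
  expect_error(rank_sum_one_sided(numeric(0), 1), "non-empty")
})

test_that("exact rank-sum matches wilcox.test for all group sizes <= 6", {
  set.seed(33)
  for (rep in 1:40) {
    n1 <- sample(1:6, 1)
    n2 <- sample(1:6, 1)
    x <- sample(seq_len(50), n1 + n2) # distinct -> no ties
    a <- x[seq_len(n1)]
    b <- x[-seq_len(n1)]
    ours <- rank_sum_one_sided(a, b)
    ref <- stats::wilcox.test(a, b, alternative = "greater", exact = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value))
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("large or tied samples use the normal approximation", {
  a <- c(rep(1, 5), 2:8)
  b <- c(rep(1, 3), 5:12)
  r <- rank_sum_one_sided(a, b)
  expect_identical(r$method, "normal_approximation")
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  ref <- suppressWarnings(stats::wilcox.test(a, b, alternative = "greater",
                                             exact = FALSE, correct = TRUE))
  expect_equal(r$p_value, unname(ref$p.value), tolerance = 1e-8)
})

test_that("pooled SAGs from distinct haplotypes recover the divergence density", {
  g <- make_genome(seed = 61, length = 40000)
  pop <- simulate_population(g, 2, 12, 14, seed = 5)
  sags <- lapply(1:2, function(h) {
    simulate_sag_reads(sag_scenario(paste0("s", h), h, coverage_mean = 60,
                                    seed = 100 + h), pop)$alignments
  })
  res <- pooling_experiment(sags, g, k_values = 1:2, seed = 9)
  div_per_kb <- haplotype_divergence(pop, 1, 2) / (40000 / 1000)
  expect_lt(res$density[1], 1)
  expect_lt(abs(res$density[2] - div_per_kb) / div_per_kb, 0.15)
})

test_that("pooling_experiment rejects under-covered SAG sets", {
  g <- make_genome(seed = 62, length = 20000)
  pop <- simulate_population(g, 2, 5, 5, seed = 2)
  deep <- simulate_sag_reads(sag_scenario("a", 1, coverage_mean = 30,
                                          seed = 1), pop)$alignments
  shallow <- simulate_sag_reads(sag_scenario("b", 2, coverage_mean = 0.2,
                                             mda_bias = 2, seed = 2),
                                pop)$alignments
  expect_error(pooling_experiment(list(deep, shallow), g, k_values = 1:2),
               "cover")
})
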