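test_that("consensus masking uses a strict >10% disagreement boundary", {
  mk <- function(...) counts_fixture(rbind(c(...)),
                                     ref = "A")
  expect_identical(as.character(consensus_alleles(mk(9L, 1L, 0L, 0L))), "A")
  expect_identical(as.character(consensus_alleles(mk(8L, 2L, 0L, 0L))), "x")
  expect_identical(as.character(consensus_alleles(mk(0L, 0L, 0L, 0L))), ".")
  # 50/50 tie -> masked
  expect_identical(as.character(consensus_alleles(mk(5L, 5L, 0L, 0L))), "x")
  # reference N -> excluded entirely
  cn <- counts_fixture(rbind(c(10L, 0L, 0L, 0L)), ref = "N")
  expect_identical(as.character(consensus_alleles(cn)), ".")
})

consensus_from <- function(chars, sag_id = "s") {
  structure(chars, sag_id = sag_id, class = "consensus_sequence")
}

test_that("cross-SAG SNP calling enforces 5-of-7 coverage and variant logic", {
  ref <- c(ref = "AAAA")
  cons <- function(...) consensus_from(c(...))
  # position 1: only 4 of 7 unmasked -> ineligible even though variant
  # position 2: 5 unmasked, all = reference -> eligible, no SNP
  # position 3: 5 unmasked, all agree on C != reference A -> SNP
  # position 4: 5 unmasked, one variant among SAGs -> SNP
  sags <- list(
    cons("C", "A", "C", "A"),
    cons("C", "A", "C", "A"),
    cons("C", "A", "C", "A"),
    cons("C", "A", "C", "C"),
    cons(".", "A", "C", "A"),
    cons("x", "x", "x", "x"),
    cons(".", ".", ".", ".")
  )
  res <- cross_sag_snps(sags, ref, min_sags = 5)
  expect_identical(res$eligible_pos, c(1L, 2L, 3L))
  expect_identical(res$snps$pos, c(2L, 3L))
  expect_identical(res$snps$major_allele, c("C", "A"))
  expect_error(cross_sag_snps(sags[1:3], ref, min_sags = 5), "exceeds")
})

test_that("raising the mask fraction never shrinks the eligible set", {
  set.seed(77)
  g <- small_genome()
  pop <- simulate_population(g, 3, 6, 6, seed = 3)
  counts <- lapply(1:3, function(h) {
    sag_site_counts(simulate_sag_reads(
      sag_scenario(paste0("s", h), h, coverage_mean = 15, error_rate = 0.01,
                   seed = h), pop)$alignments, g)
  })
  eligible <- vapply(c(0.05, 0.10, 0.25), function(mf) {
    cons <- lapply(counts, consensus_alleles, mask_fraction = mf)
    cross_sag_snps(cons, g, min_sags = 2)$n_eligible
  }, numeric(1))
  expect_true(all(diff(eligible) >= 0))
})

test_that("pN/pS follows its defining arithmetic and undefined flagging", {
  snps <- data.frame(degeneracy_class = c(rep("onefold", 10),
                                          rep("fourfold", 20)))
  r <- pn_ps(snps, c(onefold = 10000, fourfold = 3178))
  expect_equal(r$ratio, (10 / 10000) / (20 / 3178))
  expect_equal(round(r$ratio, 4), 0.1589)

  none <- data.frame(degeneracy_class = rep("fourfold", 5))
  expect_equal(pn_ps(none, c(onefold = 100, fourfold = 100))$ratio, 0)

  nos <- data.frame(degeneracy_class = rep("onefold", 5))
  u <- pn_ps(nos, c(onefold = 100, fourfold = 100))
  expect_true(u$undefined)
  expect_true(is.nan(u$ratio))
  expect_error(pn_ps(snps, c(onefold = 0, fourfold = 10)), "zero")
})

test_that("recovered sSNPs classify fourfold on error-free input", {
  g <- small_genome()
  pop <- simulate_population(g, 7, 8, 8, seed = 6)
  counts <- lapply(1:7, function(h) {
    sag_site_counts(simulate_sag_reads(
      sag_scenario(paste0("s", h), h, coverage_mean = 25, error_rate = 0,
                   mda_bias = 0.3, seed = h), pop)$alignments, g)
  })
  pd <- population_diversity(counts, g, min_sags = 5)
  truth <- pop$variants
  called <- merge(pd$snps, truth, by = "pos")
  expect_gt(nrow(called), 20)
  expect_identical(called$degeneracy_class, called$class)
})

test_that("per-gene densities use mapped sites with the >= 100 site filter", {
  g <- tiny_genome()
  genes3 <- data.frame(
    gene_id = c("big", "small"), start = c(0L, 1200L), end = c(1020L, 1299L),
    strand = "+", category = "Hypothetical", stringsAsFactors = FALSE)
  set.seed(1)
  seq3 <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                collapse = "")
  # force valid gene structure irrelevant here: lengths multiples of 3
  gg <- suppressWarnings(annotated_genome("t3", seq3, genes3))
  eligible <- 0:1399 # 1000 mapped sites in "big"? all of big + 99 of small
  eligible <- c(0:999, 1200:1298)
  snps <- data.frame(pos = c(5L, 10L, 15L, 20L, 25L),
                     degeneracy_class = "onefold")
  tab <- suppressWarnings(
    gene_snp_density(snps, eligible, gg, min_mapped_sites = 100))
  expect_identical(tab$gene_id, "big")
  expect_equal(tab$mapped_sites, 1000)
  expect_equal(tab$nsnp_density, 5 * 1000 / 1000)
})

test_that("category ANOVA excludes small categories and matches t^2 for two groups", {
  set.seed(55)
  tab <- data.frame(
    gene_id = sprintf("g%02d", 1:25),
    category = c(rep("A", 10), rep("B", 12), rep("C", 3)),
    nsnp_density = c(rnorm(10, 5), rnorm(12, 9), rnorm(3, 2))
  )
  cs <- category_anova(tab, min_genes = 10)
  expect_identical(cs$anova$df1, 1L)
  expect_identical(cs$anova$df2, 20L)
  tt <- t.test(nsnp_density ~ category, data = tab[tab$category != "C", ],
               var.equal = TRUE)
  expect_equal(cs$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(cs$anova$p, unname(tt$p.value), tolerance = 1e-10)
  # category C present in descriptives, not tested
  expect_true("C" %in% cs$summary$category)
  expect_false(cs$summary$tested[cs$summary$category == "C"])
  expect_false("C" %in% names(cs$letters))
  # well-separated groups get distinct letters
  expect_false(cs$letters[["A"]] == cs$letters[["B"]])
  expect_error(category_anova(tab, min_genes = 13), "fewer than 2")
})

test_that("region chi-square is zero under proportional placement", {
  gene <- data.frame(gene_id = "g", start = 0L, end = 300L, strand = "+",
                     category = "Hypothetical external")
  gene$regions <- list(c(rep("internal", 50), rep("external", 30),
                         rep("transmembrane", 20)))
  # nSNPs hitting 10/6/4 residues across the three regions
  res_idx <- c(1:10, 51:56, 81:84) # residues, 1-based
  pos <- (res_idx - 1L) * 3L # first codon base
  r <- region_chisq(pos, gene)
  expect_equal(r$chi2, 0)
  expect_identical(r$N, 20L)

  gene2 <- gene
  gene2$regions <- list(c(rep("internal", 50), rep("external", 50)))
  pos2 <- (0:19) * 3L # 20 nSNP residues, all internal
  r2 <- region_chisq(pos2, gene2)
  expect_equal(r2$chi2, 20)
  expect_identical(r2$df, 1L)

  gene3 <- gene
  gene3$regions <- list(rep("internal", 100))
  expect_error(region_chisq(pos2, gene3), "one non-empty")
})
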