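test_that("zero target densities give haplotypes identical to the reference", {
  g <- small_genome()
  pop <- simulate_population(g, 3, 0, 0, seed = 1)
  expect_identical(nrow(pop$variants), 0L)
  for (h in 1:3) expect_identical(haplotype_sequence(pop, h), g$sequence)
})

test_that("simulated sSNPs are synonymous and nSNPs non-synonymous by translation", {
  g <- small_genome()
  pop <- simulate_population(g, 5, 3, 3, seed = 8)
  gc <- Biostrings::getGeneticCode("11")
  genes <- g$genes
  for (i in seq_len(nrow(pop$variants))) {
    v <- pop$variants[i, ]
    gene <- genes[genes$start <= v$pos & genes$end > v$pos, ][1, ]
    gseq <- substr(g$sequence, gene$start + 1, gene$end)
    off <- if (gene$strand == "+") v$pos - gene$start
    else gene$end - 1L - v$pos
    alt <- if (gene$strand == "+") v$alt
    else as.character(Biostrings::reverseComplement(Biostrings::DNAString(v$alt)))
    if (gene$strand == "-") {
      gseq <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(gseq)))
    }
    codon_i <- off %/% 3L
    codon <- substr(gseq, codon_i * 3 + 1, codon_i * 3 + 3)
    mut <- codon
    substr(mut, off %% 3L + 1L, off %% 3L + 1L) <- alt
    if (v$class == "fourfold") {
      expect_identical(gc[[codon]], gc[[mut]])
    } else {
      expect_false(gc[[codon]] == gc[[mut]])
    }
  }
})

test_that("realized variant density tracks the target within sampling error", {
  g <- make_genome(seed = 31, length = 100000)
  pop <- simulate_population(g, 7, 8, 10, seed = 4)
  len_kb <- nchar(g$sequence) / 1000
  expect_equal(pop$realized$ssnp_count, round(8 * len_kb))
  gene_kb <- sum(g$genes$end - g$genes$start) / 1000
  expect_equal(pop$realized$nsnp_count, sum(round(
    10 * tapply(g$genes$end - g$genes$start, g$genes$category, sum) / 1000)))
  # both counts are exact by construction; densities follow
  expect_equal(pop$realized$ssnp_per_kb, pop$realized$ssnp_count / len_kb)
})

test_that("infeasible variant densities error with the available capacity", {
  g <- small_genome()
  expect_error(simulate_population(g, 3, 1000, 0, seed = 1), "fourfold sites")
  expect_error(simulate_population(g, 3, 0, 5000, seed = 1), "onefold sites")
})

test_that("ground-truth divergence equals brute-force haplotype comparison", {
  g <- small_genome()
  pop <- simulate_population(g, 4, 5, 6, seed = 12)
  for (pair in list(c(1, 2), c(2, 4))) {
    a <- strsplit(haplotype_sequence(pop, pair[1]), "")[[1]]
    b <- strsplit(haplotype_sequence(pop, pair[2]), "")[[1]]
    expect_identical(haplotype_divergence(pop, pair[1], pair[2]),
                     sum(a != b))
  }
})

test_that("error-free clonal reads are exact haplotype substrings", {
  g <- small_genome()
  pop <- simulate_population(g, 2, 5, 5, seed = 3)
  sc <- sag_scenario("s", 2, coverage_mean = 3, error_rate = 0, seed = 6)
  sim <- simulate_sag_reads(sc, pop)
  hap <- haplotype_sequence(pop, 2)
  expect_true(all(substring(hap, sim$alignments$pos + 1,
                            sim$alignments$pos + 150) == sim$alignments$seq))
})

test_that("read simulation is deterministic under a fixed seed", {
  g <- small_genome()
  pop <- simulate_population(g, 2, 5, 5, seed = 3)
  sc <- sag_scenario("s", c(1, 2), coverage_mean = 5, seed = 99)
  a <- simulate_sag_reads(sc, pop)
  b <- simulate_sag_reads(sc, pop)
  expect_identical(a$alignments, b$alignments)
  expect_identical(a$truth, b$truth)
})

test_that("a 50/50 two-haplotype mixture shows ~0.5 minor fraction at divergent sites", {
  g <- make_genome(seed = 41, length = 30000)
  pop <- simulate_population(g, 2, 10, 10, seed = 5)
  sc <- sag_scenario("mix", c(1, 2), mixture_weights = c(0.5, 0.5),
                     coverage_mean = 80, error_rate = 0, mda_bias = 0,
                     seed = 7)
  sim <- simulate_sag_reads(sc, pop)
  counts <- pileup(sim$alignments, g, min_base_q = 30)
  # variant sites carried by exactly one haplotype
  private <- pop$variants$pos[pop$variants$n_carriers == 1]
  m <- counts$counts[private + 1, , drop = FALSE]
  depth <- rowSums(m)
  keep <- depth >= 50
  expect_gt(sum(keep), 50)
  alt_i <- match(pop$variants$alt[pop$variants$n_carriers == 1], c("A", "C", "G", "T"))
  altn <- m[cbind(seq_len(nrow(m)), alt_i)]
  frac <- altn[keep] / depth[keep]
  sd3 <- 3 * sqrt(0.25 / depth[keep])
  expect_gt(mean(abs(frac - 0.5) <= sd3), 0.95)
})

test_that("shred_contigs emits exact error-free pairs at the requested coverage", {
  set.seed(2)
  contig <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                  collapse = "")
  aln <- shred_contigs(c(c1 = contig), coverage = 20, seed = 14)
  expect_identical(nrow(aln), 1334L) # ceiling(20 * 10000 / 300) pairs x 2
  expect_true(all(substring(contig, aln$pos + 1, aln$pos + 150) == aln$seq))
  expect_true(all(aln$nm == 0L))
  # recover insert size per pair: R2 start - R1 start + read length
  r1 <- aln[grepl("/1$", aln$read_id), ]
  r2 <- aln[grepl("/2$", aln$read_id), ]
  insert <- r2$pos - r1$pos + 150L
  expect_true(all(insert >= 180L & insert <= 400L))
})

test_that("shred_contigs skips short contigs with a warning", {
  expect_warning(
    aln <- shred_contigs(c(short = strrep("A", 100),
                           ok = strrep("ACGT", 500)), seed = 1),
    "short"
  )
  expect_true(all(aln$target_id == "ok"))
  expect_error(shred_contigs(c(mid = strrep("A", 300)), seed = 1),
               "insert")
})

test_that("co-sorted mixtures have binomial host fractions and exact truth labels", {
  g <- make_genome(seed = 51, length = 20000)
  host <- make_genome(seed = 52, length = 20000)
  pop <- simulate_population(g, 2, 5, 5, seed = 1)
  sc <- sag_scenario("co", 1, coverage_mean = 20, seed = 2)
  sim <- simulate_cosort(sc, pop, host, host_read_fraction = 0.5, seed = 30)
  n <- nrow(sim$alignments)
  n_host <- sum(sim$alignments$target_id == host$genome_id)
  expect_lt(abs(n_host - n / 2), 3 * sqrt(n * 0.25))
  expect_setequal(sim$truth$read_id, sim$alignments$read_id)
  expect_identical(
    sort(sim$truth$read_id[sim$truth$target_id == host$genome_id]),
    sort(sim$alignments$read_id[sim$alignments$target_id == host$genome_id])
  )
  expect_error(simulate_cosort(sc, pop, host, host_read_fraction = 0),
               "host_read_fraction")
})
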