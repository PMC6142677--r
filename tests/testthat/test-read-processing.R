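test_that("filter thresholds discard strictly-below records only", {
  # identity: NM=8 over 150 nt -> 0.9467 removed; NM=7 -> 0.9533 kept
  low_id <- one_read(nm = 8L)
  ok_id <- one_read(nm = 7L)
  expect_identical(nrow(filter_alignments(low_id)), 0L)
  expect_identical(nrow(filter_alignments(ok_id)), 1L)
  # exact boundary: identity 0.95 kept (e.g. 140 nt read with NM=7)
  boundary <- one_read(seq = strrep("A", 140), nm = 7L,
                       cigar = "140M")
  expect_identical(nrow(filter_alignments(boundary)), 1L)

  # mapq 19 removed, 20 kept
  expect_identical(nrow(filter_alignments(one_read(mapq = 19L))), 0L)
  expect_identical(nrow(filter_alignments(one_read(mapq = 20L))), 1L)

  # mean read quality 29.9 removed, 30 kept
  q30 <- one_read(qual = qual_string(rep(30, 150)))
  q29 <- one_read(qual = qual_string(c(rep(30, 149), 15)))
  expect_identical(nrow(filter_alignments(q30)), 1L)
  expect_identical(nrow(filter_alignments(q29)), 0L)
})

test_that("filtering is idempotent and logs per-filter removals", {
  set.seed(4)
  g <- small_genome()
  pop <- simulate_population(g, 2, 8, 8, seed = 2)
  sim <- simulate_sag_reads(sag_scenario("s", 1, coverage_mean = 10,
                                         error_rate = 0.02, seed = 3), pop)
  f1 <- filter_alignments(sim$alignments)
  f2 <- filter_alignments(f1)
  for (col in names(f1)) expect_identical(f1[[col]], f2[[col]])
  expect_identical(sum(attr(f2, "filter_log")), 0L)
  log <- attr(f1, "filter_log")
  expect_named(log, c("low_identity", "low_read_quality", "low_mapq"))
})

test_that("pileup counts only bases at or above the quality threshold", {
  aln <- one_read(pos = 0L, seq = "ACGT", qual = qual_string(c(40, 40, 29, 40)),
                  cigar = "4M")
  counts <- pileup(aln, c(tiny = "ACGTACGT"))
  expect_identical(unname(counts$counts[3, ]), rep(0L, 4)) # q29 excluded
  expect_identical(unname(counts$counts[1, "A"]), 1L)
  expect_identical(unname(counts$counts[4, "T"]), 1L)
})

test_that("pileup handles depth, insertions and overhangs", {
  aln <- rbind(one_read(pos = 0L, seq = "ACGT", cigar = "4M",
                        qual = "IIII"),
               one_read(pos = 0L, seq = "ACGT", cigar = "4M",
                        qual = "IIII", read_id = "r2"))
  class(aln) <- c("alignment_table", "data.frame")
  counts <- pileup(aln, c(tiny = "ACGTACGT"))
  expect_identical(unname(rowSums(counts$counts)[1:4]), rep(2, 4))

  # 2M1I2M: 5 read bases over 4 reference positions
  ins <- one_read(pos = 0L, seq = "ACTGT", cigar = "2M1I2M",
                  qual = "IIIII")
  ci <- pileup(ins, c(tiny = "ACGTACGT"))
  expect_identical(sum(ci$counts), 4L)
  expect_identical(unname(rowSums(ci$counts)[1:4]), rep(1, 4))

  over <- one_read(pos = 6L, seq = "ACGT", cigar = "4M", qual = "IIII",
                   read_id = "hang")
  expect_error(pileup(over, c(tiny = "ACGTACGT")), "hang")
})

test_that("pileup conserves counted bases across reads", {
  set.seed(9)
  g <- small_genome()
  pop <- simulate_population(g, 2, 5, 5, seed = 2)
  sim <- simulate_sag_reads(sag_scenario("s", 1, coverage_mean = 8,
                                         error_rate = 0.01, seed = 4), pop)
  flt <- filter_alignments(sim$alignments)
  counts <- pileup(flt, g, min_base_q = 30)
  phred <- lapply(strsplit(flt$qual, ""), function(ch)
    as.integer(charToRaw(paste(ch, collapse = ""))) - 33L)
  expected <- sum(vapply(phred, function(q) sum(q >= 30L), integer(1)))
  expect_identical(sum(counts$counts), expected)
})

test_that("downsampling fixes depth, drops shallow sites and preserves MAF in expectation", {
  mat <- matrix(0L, nrow = 3, ncol = 4)
  mat[1, ] <- c(60L, 20L, 0L, 0L) # depth 80
  mat[2, ] <- c(49L, 0L, 0L, 0L)  # depth 49 -> dropped
  mat[3, ] <- c(25L, 25L, 0L, 0L) # depth 50 boundary -> kept
  counts <- counts_fixture(mat)
  down <- downsample_sites(counts, target_depth = 50, seed = 21)
  expect_identical(unname(rowSums(down$counts)), c(50, 0, 50))
  expect_identical(down$flag[2], "dropped_low_depth")
  expect_identical(down$flag[3], "covered")

  same <- downsample_sites(counts, target_depth = 50, seed = 21)
  expect_identical(down$counts, same$counts)

  # unbiasedness: mean downsampled minor fraction ~ 0.25 over many seeds
  fracs <- vapply(1:400, function(s) {
    d <- downsample_sites(counts, target_depth = 50, seed = s)
    d$counts[1, "C"] / 50
  }, numeric(1))
  # hypergeometric sd of the mean over 400 draws
  sd_mean <- sqrt(0.25 * 0.75 / 50 * (80 - 50) / (80 - 1)) / sqrt(400)
  expect_lt(abs(mean(fracs) - 0.25), 3 * sd_mean)
})

test_that("pooling takes floor(depth/k) from every SAG and needs full coverage", {
  mk <- function(a, c) counts_fixture(matrix(c(a, c, 0L, 0L), nrow = 1))
  # k = 3, target 50 -> 16 each, pooled depth 48
  pooled <- pool_counts(list(mk(100L, 0L), mk(0L, 100L), mk(50L, 50L)),
                        target_depth = 50, seed = 2)
  expect_identical(unname(rowSums(pooled$counts)), 48)
  expect_identical(pooled$target_depth, 48L)

  # one SAG below floor(50/2) = 25 at the site -> excluded
  short <- pool_counts(list(mk(100L, 0L), mk(10L, 0L)), target_depth = 50,
                       seed = 2)
  expect_identical(short$flag[1], "dropped_low_depth")
  expect_identical(unname(rowSums(short$counts)), 0)

  expect_error(pool_counts(rep(list(mk(10L, 0L)), 51), target_depth = 50),
               "target depth")
})

test_that("pooling one SAG reduces to plain downsampling", {
  set.seed(8)
  mat <- matrix(as.integer(rmultinom(200, 120, c(0.6, 0.3, 0.08, 0.02))),
                ncol = 4, byrow = TRUE)
  counts <- counts_fixture(mat)
  a <- downsample_sites(counts, target_depth = 50, seed = 77)
  b <- pool_counts(list(counts), target_depth = 50, seed = 77)
  expect_identical(a$counts, b$counts)
  expect_identical(a$flag, b$flag)
})
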