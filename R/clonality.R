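#' Call SNPs from downsampled site counts
#'
#' At every covered site, the major allele is the most frequent base and
#' the minor allele the second most frequent; a SNP is emitted iff the
#' minor allele frequency (minor count / depth) is at least `maf_min`
#' (inclusive). Multi-allelic sites emit a single record with the top
#' minor allele. Requires uniform depth, i.e. downsampled or pooled input.
#'
#' @param counts A [site_counts()] after [downsample_sites()] or
#'   [pool_counts()].
#' @param maf_min Minimum minor allele frequency (inclusive).
#' @return A SNP table: `data.frame` with `target_id`, `pos` (0-based),
#'   `ref_allele`, `major_allele`, `minor_allele`, `minor_count`,
#'   `depth_used`, `maf`, `degeneracy_class` (`NA` until
#'   [classify_snps()]), `gene_id`.
#' @export
call_snps <- function(counts, maf_min = 0.10) {
  stopifnot(inherits(counts, "site_counts"))
  if (is.null(counts$target_depth)) {
    stop("call_snps needs downsampled or pooled counts (uniform depth); ",
         "run downsample_sites() or pool_counts() first")
  }
  m <- counts$counts
  covered <- counts$flag == "covered" & rowSums(m) > 0L
  depth <- counts$target_depth
  if (any(rowSums(m[covered, , drop = FALSE]) != depth)) {
    stop("covered sites do not all have the uniform target depth")
  }
  sub <- m[covered, , drop = FALSE]
  ord1 <- max.col(sub, ties.method = "first")
  top1 <- sub[cbind(seq_len(nrow(sub)), ord1)]
  sub2 <- sub
  sub2[cbind(seq_len(nrow(sub)), ord1)] <- -1L
  ord2 <- max.col(sub2, ties.method = "first")
  top2 <- sub[cbind(seq_len(nrow(sub)), ord2)]
  maf <- top2 / depth
  is_snp <- maf >= maf_min
  pos0 <- which(covered)[is_snp] - 1L
  snp_table(
    target_id = counts$target_id, pos = pos0,
    ref_allele = counts$refbase[pos0 + 1L],
    major_allele = DNA_BASES[ord1[is_snp]],
    minor_allele = DNA_BASES[ord2[is_snp]],
    minor_count = top2[is_snp], depth_used = depth,
    maf = maf[is_snp]
  )
}

snp_table <- function(target_id = character(), pos = integer(),
                      ref_allele = character(), major_allele = character(),
                      minor_allele = character(), minor_count = integer(),
                      depth_used = integer(), maf = numeric(),
                      degeneracy_class = NA_character_,
                      gene_id = NA_character_) {
  n <- length(pos)
  data.frame(
    target_id = rep_len(as.character(target_id), n), pos = as.integer(pos),
    ref_allele = as.character(ref_allele),
    major_allele = as.character(major_allele),
    minor_allele = as.character(minor_allele),
    minor_count = as.integer(minor_count),
    depth_used = rep_len(as.integer(depth_used), n), maf = as.numeric(maf),
    degeneracy_class = rep_len(as.character(degeneracy_class), n),
    gene_id = rep_len(as.character(gene_id), n),
    stringsAsFactors = FALSE
  )
}

#' SNP density per kilobase of covered sites
#'
#' Density = SNP count x 1000 / number of covered sites. The denominator
#' is sites surviving downsampling, not assembly length, so densities are
#' comparable across unevenly covered SAGs.
#'
#' @param snps A SNP table from [call_snps()].
#' @param counts The [site_counts()] the SNPs were called from.
#' @param unit_id Label for the density record (defaults to the target).
#' @return One-row `data.frame`: `unit_id`, `snp_count`, `covered_kb`,
#'   `density`.
#' @export
snp_density <- function(snps, counts, unit_id = counts$target_id) {
  stopifnot(inherits(counts, "site_counts"))
  if (nrow(snps) > 0L && !all(snps$target_id == counts$target_id)) {
    stop("SNP table and site counts are on different targets")
  }
  covered <- sum(counts$flag == "covered" & rowSums(counts$counts) > 0L)
  if (covered == 0L) stop("zero covered sites; no density defined")
  data.frame(unit_id = unit_id, snp_count = nrow(snps),
             covered_kb = covered / 1000,
             density = nrow(snps) * 1000 / covered,
             stringsAsFactors = FALSE)
}

#' One-sided Wilcoxon rank-sum test
#'
#' Exact p-value by full enumeration of all `choose(n1 + n2, n1)` rank
#' assignments when `n1 + n2 <= 12` and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#' The alternative is "a stochastically greater than b".
#'
#' @param a,b Numeric vectors (e.g. SNP densities per group).
#' @param alternative Only `"a_greater"` is implemented; use
#'   `rank_sum_one_sided(b, a)` for the other direction.
#' @return A list of class `rank_sum_result`: `statistic` (Mann-Whitney U
#'   for group a), `p_value`, `n1`, `n2`, `method`.
#' @export
rank_sum_one_sided <- function(a, b, alternative = c("a_greater")) {
  alternative <- match.arg(alternative)
  n1 <- length(a)
  n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) # rank sum of group a
  u_obs <- w_obs - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && n1 + n2 <= 12L) {
    combos <- utils::combn(n1 + n2, n1)
    wdist <- colSums(matrix(seq_len(n1 + n2)[combos], nrow = n1))
    p <- mean(wdist >= w_obs)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                                (n * (n - 1)))
    z <- (u_obs - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal_approximation"
  }
  structure(list(statistic = u_obs, p_value = p, n1 = n1, n2 = n2,
                 method = method),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("One-sided Wilcoxon rank-sum (%s): U = %g, n = (%d, %d), p = %.4g\n",
              x$method, x$statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Pooled-SAG SNP density experiment
#'
#' Calibrates the SNP-density signal expected from multiple distinct
#' attached cells: SAG alignments are filtered, SAGs covering more than
#' `min_ref_coverage` of the reference (fraction of positions with at
#' least one filtered read) are retained, and for each k in `k_values`
#' reads from the first k SAGs (input order) are pooled with equal
#' per-SAG contribution, downsampled and SNP-called.
#'
#' @param sag_alignments List of [alignment_table()], one per SAG.
#' @param reference The shared reference [annotated_genome()].
#' @param k_values Pool sizes to evaluate.
#' @param min_ref_coverage Retention threshold on reference coverage
#'   (strictly greater than).
#' @param target_depth Per-site pooled depth budget.
#' @param maf_min SNP-calling minor allele frequency threshold.
#' @param min_base_q Pileup base-quality threshold.
#' @param seed Integer seed or `NULL`.
#' @param ... Passed to [filter_alignments()].
#' @return `data.frame` with one row per k: `k`, `snp_count`, `covered_kb`,
#'   `density`.
#' @export
pooling_experiment <- function(sag_alignments, reference,
                               k_values = seq_along(sag_alignments),
                               min_ref_coverage = 0.25, target_depth = 50L,
                               maf_min = 0.10, min_base_q = 30, seed = NULL,
                               ...) {
  counts_list <- lapply(sag_alignments, function(aln) {
    pileup(filter_alignments(aln, ...), reference, min_base_q = min_base_q)
  })
  coverage <- vapply(counts_list, function(x) {
    mean(rowSums(x$counts) > 0L)
  }, numeric(1))
  keep <- coverage > min_ref_coverage
  if (sum(keep) < max(k_values)) {
    stop("only ", sum(keep), " SAGs cover more than ",
         min_ref_coverage * 100, "% of the reference (coverages: ",
         paste(sprintf("%.3f", coverage), collapse = ", "),
         "); max k requested is ", max(k_values))
  }
  counts_list <- counts_list[keep]
  with_seed(seed, {
    res <- lapply(k_values, function(k) {
      pooled <- pool_counts(counts_list[seq_len(k)],
                            target_depth = target_depth)
      snps <- call_snps(pooled, maf_min = maf_min)
      d <- snp_density(snps, pooled, unit_id = paste0("pool_k", k))
      data.frame(k = k, snp_count = d$snp_count, covered_kb = d$covered_kb,
                 density = d$density)
    })
    do.call(rbind, res)
  })
}
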