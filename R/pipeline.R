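#' Filter + pileup convenience chain for one SAG
#'
#' @param aln Raw [alignment_table()] for one SAG.
#' @param reference The [annotated_genome()] mapped against.
#' @param min_identity,min_mean_read_q,min_mapq See [filter_alignments()].
#' @param min_base_q See [pileup()].
#' @return A [site_counts()] object.
#' @export
sag_site_counts <- function(aln, reference, min_identity = 0.95,
                            min_mean_read_q = 30, min_mapq = 20,
                            min_base_q = 30) {
  flt <- filter_alignments(aln, min_identity = min_identity,
                           min_mean_read_q = min_mean_read_q,
                           min_mapq = min_mapq)
  pileup(flt, reference, min_base_q = min_base_q)
}

#' Within-SAG SNP density (clonality signal)
#'
#' The full per-SAG chain: filter, pileup, downsample to a fixed per-site
#' depth, call SNPs at the MAF threshold, and report SNPs per kb of
#' covered sites. A clonal (single-cell) SAG yields a density near the
#' residual error baseline; a mixture of diverged cells yields a density
#' near their true divergence.
#'
#' @param aln Raw [alignment_table()] for one SAG.
#' @param reference The [annotated_genome()] mapped against.
#' @param target_depth Per-site downsampling depth.
#' @param maf_min Minor allele frequency threshold.
#' @param seed Integer seed or `NULL`.
#' @param ... Passed to [sag_site_counts()].
#' @return A list: `density` (one-row density record), `snps` (SNP table),
#'   `counts` (downsampled [site_counts()]).
#' @export
sag_snp_density <- function(aln, reference, target_depth = 50L,
                            maf_min = 0.10, seed = NULL, ...) {
  counts <- sag_site_counts(aln, reference, ...)
  down <- downsample_sites(counts, target_depth = target_depth, seed = seed)
  snps <- call_snps(down, maf_min = maf_min)
  list(density = snp_density(snps, down, unit_id = counts$target_id),
       snps = snps, counts = down)
}

#' Multi-SAG population diversity analysis
#'
#' The consensus-based population chain: per-SAG consensus alleles with
#' ambiguity masking, cross-SAG SNP calling at positions covered by at
#' least `min_sags` SAGs, degeneracy classification, pN/pS over
#' fourfold/onefold degenerate sites, and per-gene densities over mapped
#' sites.
#'
#' @param counts_list List of per-SAG [site_counts()] (filtered, full
#'   depth; see [sag_site_counts()]).
#' @param genome The shared reference [annotated_genome()].
#' @param min_sags Minimum SAGs covering a site for eligibility.
#' @param mask_fraction Consensus masking threshold.
#' @param min_mapped_sites Per-gene mapped-sites threshold.
#' @param classes Optional precomputed [classify_genome_sites()] result.
#' @return A list of class `population_diversity`: `snps` (classified SNP
#'   table), `n_eligible`, `eligible_by_class`, `pnps` ([pn_ps()] result),
#'   `gene_table` ([gene_snp_density()] result), `snp_density_per_kb`
#'   (genome-wide SNPs per kb of eligible sites).
#' @export
population_diversity <- function(counts_list, genome, min_sags = 5L,
                                 mask_fraction = 0.10,
                                 min_mapped_sites = 100L,
                                 classes = classify_genome_sites(genome)) {
  consensuses <- lapply(counts_list, consensus_alleles,
                        mask_fraction = mask_fraction)
  cross <- cross_sag_snps(consensuses, genome, min_sags = min_sags)
  snps <- classify_snps(cross$snps, genome, classes = classes)
  by_class <- eligible_site_classes(cross$eligible_pos, genome,
                                    classes = classes)
  pnps <- pn_ps(snps, by_class)
  gene_table <- gene_snp_density(snps, cross$eligible_pos, genome,
                                 min_mapped_sites = min_mapped_sites,
                                 classes = classes)
  structure(list(
    snps = snps, n_eligible = cross$n_eligible,
    eligible_by_class = by_class, pnps = pnps, gene_table = gene_table,
    snp_density_per_kb = nrow(snps) * 1000 / cross$n_eligible
  ), class = "population_diversity")
}

#' @export
print.population_diversity <- function(x, ...) {
  cat(sprintf(paste0("<population_diversity> %d SNPs over %d eligible ",
                     "sites (%.2f per kb)\n"), nrow(x$snps), x$n_eligible,
              x$snp_density_per_kb))
  print(x$pnps)
  invisible(x)
}
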