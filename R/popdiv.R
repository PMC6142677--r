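#' Per-SAG consensus alleles with ambiguity masking
#'
#' The consensus at each position is the modal allele of the (filtered,
#' not downsampled) base counts. A site is MASKED when more than
#' `mask_fraction` of its reads differ from the modal allele (strictly
#' greater than), or when the modal allele is tied; positions with no
#' coverage are NOCOV. Symbols: `A/C/G/T`, `x` = MASKED, `.` = NOCOV.
#'
#' @param counts A [site_counts()] object (filtered, full depth).
#' @param mask_fraction Masking threshold on the fraction of disagreeing
#'   reads.
#' @param sag_id Identifier stored on the result.
#' @return Character vector of per-position symbols, class
#'   `consensus_sequence`, with attribute `sag_id`.
#' @export
consensus_alleles <- function(counts, mask_fraction = 0.10,
                              sag_id = counts$target_id) {
  stopifnot(inherits(counts, "site_counts"))
  m <- counts$counts
  d <- rowSums(m)
  top_i <- max.col(m, ties.method = "first")
  top <- m[cbind(seq_len(nrow(m)), top_i)]
  # tie on the modal allele: another base reaches the same count
  tied <- rowSums(m == top) > 1L & top > 0L
  cons <- DNA_BASES[top_i]
  masked <- d > 0L & ((d - top) / d > mask_fraction | tied)
  cons[masked] <- "x"
  cons[d == 0L] <- "."
  cons[counts$flag == "reference_N"] <- "."
  structure(cons, sag_id = sag_id, class = "consensus_sequence")
}

#' Cross-SAG SNP calling from consensus sequences
#'
#' A position is eligible when at least `min_sags` consensuses are
#' unmasked (A/C/G/T) there; a SNP is emitted when the eligible consensus
#' alleles together with the reference allele contain at least two
#' distinct bases — i.e. at least one SAG shows a variant relative to the
#' other SAGs or to the reference.
#'
#' @param consensuses List of [consensus_alleles()] results on the same
#'   reference coordinate system.
#' @param reference The reference [annotated_genome()] (or sequence
#'   string).
#' @param min_sags Minimum number of unmasked SAGs per eligible site.
#' @return A list of class `cross_sag_result`: `snps` (SNP table),
#'   `eligible_pos` (0-based eligible positions), `n_eligible`.
#' @export
cross_sag_snps <- function(consensuses, reference, min_sags = 5L) {
  if (min_sags > length(consensuses)) {
    stop("min_sags (", min_sags, ") exceeds the number of SAGs (",
         length(consensuses), ")")
  }
  refseq <- if (inherits(reference, "annotated_genome")) reference$sequence
  else toupper(as.character(reference))
  target_id <- if (inherits(reference, "annotated_genome"))
    reference$genome_id else "reference"
  len <- nchar(refseq)
  stopifnot(all(lengths(consensuses) == len))
  mat <- do.call(rbind, lapply(consensuses, as.character))
  refbase <- intToUtf8(utf8ToInt(refseq), multiple = TRUE)

  base_counts <- matrix(vapply(DNA_BASES, function(b) colSums(mat == b),
                               numeric(len)),
                        nrow = len, ncol = 4L,
                        dimnames = list(NULL, DNA_BASES))
  unmasked <- rowSums(base_counts)
  eligible <- unmasked >= min_sags & refbase %in% DNA_BASES
  present <- base_counts > 0L
  ref_idx <- match(refbase, DNA_BASES)
  has_ref <- !is.na(ref_idx)
  present[cbind(which(has_ref), ref_idx[has_ref])] <- TRUE
  distinct <- rowSums(present)
  is_snp <- eligible & distinct >= 2L

  idx <- which(is_snp)
  bc <- base_counts[idx, , drop = FALSE]
  ord1 <- max.col(bc, ties.method = "first")
  top1 <- bc[cbind(seq_along(idx), ord1)]
  bc2 <- bc
  bc2[cbind(seq_along(idx), ord1)] <- -1L
  ord2 <- max.col(bc2, ties.method = "first")
  top2 <- bc[cbind(seq_along(idx), ord2)]
  minor_allele <- ifelse(top2 > 0L, DNA_BASES[ord2], refbase[idx])
  snps <- snp_table(
    target_id = target_id, pos = idx - 1L, ref_allele = refbase[idx],
    major_allele = DNA_BASES[ord1], minor_allele = minor_allele,
    minor_count = pmax(top2, 0L), depth_used = unmasked[idx],
    maf = pmax(top2, 0L) / unmasked[idx]
  )
  structure(list(snps = snps, eligible_pos = which(eligible) - 1L,
                 n_eligible = sum(eligible)),
            class = "cross_sag_result")
}

#' Fill degeneracy classes on a SNP table
#'
#' SNPs at fourfold degenerate sites are synonymous (sSNPs), SNPs at
#' onefold degenerate sites non-synonymous (nSNPs); `other_coding` and
#' `intergenic` SNPs are tallied but excluded from pN/pS.
#'
#' @param snps A SNP table.
#' @param genome The [annotated_genome()] providing gene models.
#' @param classes Optional precomputed [classify_genome_sites()] result.
#' @return The SNP table with `degeneracy_class` and `gene_id` filled.
#' @export
classify_snps <- function(snps, genome,
                          classes = classify_genome_sites(genome)) {
  snps$degeneracy_class <- as.character(classes[snps$pos + 1L])
  snps$gene_id <- attr(classes, "gene_id")[snps$pos + 1L]
  snps
}

#' pN/pS from classified SNPs and eligible site counts
#'
#' pN/pS = (nSNPs per onefold degenerate site) / (sSNPs per fourfold
#' degenerate site), both restricted to the same eligible (covered)
#' positions. Two- and threefold degenerate sites are wholly excluded, so
#' this is the strict polymorphism ratio, not Nei-Gojobori dN/dS.
#'
#' @param classified A [classify_snps()] result.
#' @param eligible_sites_by_class Named counts of eligible sites with at
#'   least `fourfold` and `onefold` entries (see
#'   [eligible_site_classes()]).
#' @return A list of class `pnps_result`: `n_snps`, `s_snps`,
#'   `onefold_sites`, `fourfold_sites`, `pn`, `ps`, `ratio`, `undefined`.
#'   When no sSNPs are observed the ratio is `NaN` with
#'   `undefined = TRUE`, never 0.
#' @export
pn_ps <- function(classified, eligible_sites_by_class) {
  onefold_sites <- unname(eligible_sites_by_class["onefold"])
  fourfold_sites <- unname(eligible_sites_by_class["fourfold"])
  if (is.na(onefold_sites) || is.na(fourfold_sites) ||
      onefold_sites == 0 || fourfold_sites == 0) {
    stop("zero eligible onefold or fourfold sites; pN/pS undefined")
  }
  n_snps <- sum(classified$degeneracy_class == "onefold")
  s_snps <- sum(classified$degeneracy_class == "fourfold")
  pn <- n_snps / onefold_sites
  ps <- s_snps / fourfold_sites
  undefined <- s_snps == 0L
  structure(list(n_snps = n_snps, s_snps = s_snps,
                 onefold_sites = onefold_sites,
                 fourfold_sites = fourfold_sites, pn = pn, ps = ps,
                 ratio = if (undefined) NaN else pn / ps,
                 undefined = undefined),
            class = "pnps_result")
}

#' @export
print.pnps_result <- function(x, ...) {
  cat(sprintf(paste0("pN/pS: %d nSNPs / %d onefold sites = %.4g; ",
                     "%d sSNPs / %d fourfold sites = %.4g; ratio = %.4g%s\n"),
              x$n_snps, x$onefold_sites, x$pn, x$s_snps, x$fourfold_sites,
              x$ps, x$ratio, if (x$undefined) " (undefined: no sSNPs)" else ""))
  invisible(x)
}

#' Tally eligible sites by degeneracy class
#'
#' @param eligible_pos 0-based positions eligible for SNP calling (e.g.
#'   from [cross_sag_snps()]).
#' @param genome The [annotated_genome()].
#' @param classes Optional precomputed [classify_genome_sites()] result.
#' @return Named integer vector over `fourfold`, `onefold`, `other_coding`,
#'   `intergenic`.
#' @export
eligible_site_classes <- function(eligible_pos, genome,
                                  classes = classify_genome_sites(genome)) {
  cls <- classes[eligible_pos + 1L]
  vapply(c("fourfold", "onefold", "other_coding", "intergenic"),
         function(k) sum(cls == k), integer(1))
}

#' Per-gene SNP densities over mapped sites
#'
#' For every gene: mapped sites = eligible positions within the gene; the
#' nSNP (sSNP) density is the nSNP (sSNP) count x 1000 / mapped sites.
#' Genes with fewer than `min_mapped_sites` mapped sites are excluded.
#'
#' @param classified A [classify_snps()] result.
#' @param eligible_pos 0-based eligible positions.
#' @param genome The [annotated_genome()].
#' @param min_mapped_sites Minimum mapped sites per reported gene.
#' @param classes Optional precomputed [classify_genome_sites()] result.
#' @return `data.frame`: `gene_id`, `category`, `mapped_sites`, `n_snps`,
#'   `s_snps`, `nsnp_density`, `ssnp_density`.
#' @export
gene_snp_density <- function(classified, eligible_pos, genome,
                             min_mapped_sites = 100L,
                             classes = classify_genome_sites(genome)) {
  genes <- genome$genes
  n <- nrow(genes)
  gid <- attr(classes, "gene_id")
  count_by_gene <- function(pos0) {
    g <- gid[pos0 + 1L]
    tab <- table(g[!is.na(g)])
    as.integer(tab[genes$gene_id]) |>
      (\(x) ifelse(is.na(x), 0L, x))()
  }
  mapped <- count_by_gene(eligible_pos)
  nn <- count_by_gene(classified$pos[classified$degeneracy_class == "onefold"])
  ss <- count_by_gene(classified$pos[classified$degeneracy_class == "fourfold"])
  out <- data.frame(gene_id = genes$gene_id, category = genes$category,
                    mapped_sites = mapped, n_snps = nn, s_snps = ss,
                    nsnp_density = nn * 1000 / mapped,
                    ssnp_density = ss * 1000 / mapped,
                    stringsAsFactors = FALSE)
  out[out$mapped_sites >= min_mapped_sites, , drop = FALSE]
}

#' Compare SNP densities between functional categories
#'
#' One-way ANOVA on per-gene densities across functional categories with
#' at least `min_genes` genes, followed by post hoc Tukey HSD and a
#' compact letter display (greedy colouring of the non-significance
#' graph at `alpha`). Categories below `min_genes` appear in the
#' descriptive table but are excluded from the tests.
#'
#' @param gene_table A [gene_snp_density()] result.
#' @param min_genes Minimum genes per tested category.
#' @param value Column to analyse (default nSNP density).
#' @param alpha Significance level for the letter display.
#' @return A list of class `category_stats`: `summary` (per-category
#'   descriptives), `anova` (`F`, `df1`, `df2`, `p`), `tukey` (pairwise
#'   adjusted p table), `letters` (named letter groups).
#' @export
category_anova <- function(gene_table, min_genes = 10L,
                           value = "nsnp_density", alpha = 0.05) {
  stopifnot(value %in% names(gene_table))
  tab <- table(gene_table$category)
  summary_df <- do.call(rbind, lapply(names(tab), function(cat) {
    v <- gene_table[[value]][gene_table$category == cat]
    data.frame(category = cat, n_genes = length(v), mean = mean(v),
               median = stats::median(v), tested = length(v) >= min_genes,
               stringsAsFactors = FALSE)
  }))
  qualifying <- names(tab)[tab >= min_genes]
  if (length(qualifying) < 2L) {
    stop("fewer than 2 categories with at least ", min_genes, " genes")
  }
  sub <- gene_table[gene_table$category %in% qualifying, , drop = FALSE]
  sub$category <- factor(sub$category)
  fit <- stats::aov(stats::reformulate("category", value), data = sub)
  an <- summary(fit)[[1]]
  tukey <- stats::TukeyHSD(fit)$category
  letters <- letter_groups(tukey, levels(sub$category),
                           means = tapply(sub[[value]], sub$category, mean),
                           alpha = alpha)
  structure(list(
    summary = summary_df,
    anova = list(F = an[["F value"]][1], df1 = as.integer(an[["Df"]][1]),
                 df2 = as.integer(an[["Df"]][2]), p = an[["Pr(>F)"]][1]),
    tukey = tukey, letters = letters
  ), class = "category_stats")
}

# Compact letter display: categories in descending mean order; each joins
# every existing letter whose members it is not significantly different
# from, else opens a new letter.
letter_groups <- function(tukey, categories, means, alpha = 0.05) {
  sig <- function(a, b) {
    key <- paste(a, b, sep = "-")
    key2 <- paste(b, a, sep = "-")
    p <- if (key %in% rownames(tukey)) tukey[key, "p adj"]
    else tukey[key2, "p adj"]
    !is.na(p) && p < alpha
  }
  ord <- names(sort(means, decreasing = TRUE))
  groups <- list()
  for (cat in ord) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (!any(vapply(groups[[g]], function(x) sig(cat, x), logical(1)))) {
        groups[[g]] <- c(groups[[g]], cat)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- cat
  }
  out <- stats::setNames(rep("", length(categories)), categories)
  for (g in seq_along(groups)) {
    for (cat in groups[[g]]) {
      out[cat] <- paste0(out[cat], letters[g])
    }
  }
  out[ord]
}

#' @export
print.category_stats <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n", x$anova$df1,
              x$anova$df2, x$anova$F, x$anova$p))
  lg <- x$letters
  cat("Letter groups:", paste(sprintf("%s=%s", names(lg), lg),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Chi-square test of nSNP placement across protein regions
#'
#' Goodness-of-fit of the observed number of nSNP-bearing residues per
#' region class (internal / external / transmembrane) against expectation
#' proportional to region residue counts. Region classes with no residues
#' are dropped; at least two non-empty classes are required.
#'
#' @param nsnp_positions 0-based genomic positions of nSNPs in the gene.
#' @param gene One row of an [annotated_genome()] `genes` table carrying a
#'   `regions` label vector.
#' @return A list of class `region_chisq_result`: `chi2`, `df`, `p`, `N`
#'   (nSNP-bearing residues), `observed`, `expected`.
#' @export
region_chisq <- function(nsnp_positions, gene) {
  regions <- if (is.list(gene$regions)) gene$regions[[1]] else gene$regions
  if (is.null(regions)) stop("gene has no region labels")
  glen <- gene$end - gene$start
  stopifnot(length(regions) == glen %/% 3L)
  inside <- nsnp_positions >= gene$start & nsnp_positions < gene$end
  pos <- nsnp_positions[inside]
  residue <- if (gene$strand == "+") (pos - gene$start) %/% 3L + 1L
  else (gene$end - 1L - pos) %/% 3L + 1L
  residue <- unique(residue)
  region_sizes <- table(regions)
  region_sizes <- region_sizes[region_sizes > 0L]
  if (length(region_sizes) < 2L) {
    stop("only one non-empty region class; chi-square undefined (df 0)")
  }
  observed <- vapply(names(region_sizes), function(r) {
    sum(regions[residue] == r)
  }, integer(1))
  N <- length(residue)
  expected <- N * as.numeric(region_sizes) / sum(region_sizes)
  chi2 <- if (N > 0L) sum((observed - expected)^2 / expected) else 0
  df <- length(region_sizes) - 1L
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE), N = N,
                 observed = observed,
                 expected = stats::setNames(expected, names(region_sizes))),
            class = "region_chisq_result")
}

#' @export
print.region_chisq_result <- function(x, ...) {
  cat(sprintf("chi-square(%d, N = %d) = %.5g, p = %.4g\n", x$df, x$N,
              x$chi2, x$p))
  invisible(x)
}
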