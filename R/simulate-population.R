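#' Simulate a haplotype population with controlled selection signature
#'
#' Places synonymous variants (sSNPs) only at fourfold degenerate sites and
#' non-synonymous variants (nSNPs) only at onefold degenerate sites of the
#' reference, so the true pN/pS of the population is known exactly. Each
#' variant gets a population frequency drawn from `freq_spectrum` and is
#' carried by the corresponding number of haplotypes.
#'
#' @param genome Reference [annotated_genome()].
#' @param n_haplotypes Number of haplotypes (>= 2).
#' @param target_ssnp_per_kb Target sSNP count per kb of genome length.
#' @param target_nsnp_per_kb_by_category Either a single rate applied to all
#'   functional categories or a named vector of per-category rates; rates
#'   are nSNPs per kb of that category's total gene length.
#' @param freq_spectrum Population frequencies to sample variants from;
#'   default the uniform exchangeable spectrum `{1/n, ..., (n-1)/n}`.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `haplotype_population`: the reference, a
#'   variant table (`pos`, `ref`, `alt`, `class`, `category`, `freq`,
#'   `n_carriers`), per-variant carrier sets, per-haplotype variant sets,
#'   and the realized truth (`ssnp_per_kb`, `nsnp_per_kb`, site totals,
#'   `true_pnps`).
#' @export
simulate_population <- function(genome, n_haplotypes, target_ssnp_per_kb,
                                target_nsnp_per_kb_by_category,
                                freq_spectrum = NULL, seed = NULL) {
  stopifnot(inherits(genome, "annotated_genome"), n_haplotypes >= 2,
            target_ssnp_per_kb >= 0,
            all(target_nsnp_per_kb_by_category >= 0))
  with_seed(seed, {
    len <- nchar(genome$sequence)
    classes <- classify_genome_sites(genome)
    gene_of <- attr(classes, "gene_id")
    fourfold_pos <- which(classes == "fourfold") # 1-based
    onefold_pos <- which(classes == "onefold")

    n_s <- round(target_ssnp_per_kb * len / 1000)
    if (n_s > length(fourfold_pos)) {
      stop("requested sSNP density needs ", n_s, " fourfold sites but only ",
           length(fourfold_pos), " are available")
    }

    genes <- genome$genes
    cats <- unique(genes$category)
    rates <- target_nsnp_per_kb_by_category
    if (is.null(names(rates))) {
      stopifnot(length(rates) == 1L)
      rates <- stats::setNames(rep(rates, length(cats)), cats)
    }
    cat_of_gene <- stats::setNames(genes$category, genes$gene_id)
    onefold_cat <- cat_of_gene[gene_of[onefold_pos]]
    gene_len_by_cat <- tapply(genes$end - genes$start, genes$category, sum)

    n_pos <- integer(0)
    for (cat in names(rates)) {
      if (!cat %in% cats) next
      want <- round(rates[[cat]] * gene_len_by_cat[[cat]] / 1000)
      avail <- onefold_pos[!is.na(onefold_cat) & onefold_cat == cat]
      if (want > length(avail)) {
        stop("requested nSNP density for category '", cat, "' needs ", want,
             " onefold sites but only ", length(avail), " are available")
      }
      if (want > 0) n_pos <- c(n_pos, sample(avail, want))
    }
    s_pos <- if (n_s > 0) sample(fourfold_pos, n_s) else integer(0)

    pos1 <- c(s_pos, n_pos) # 1-based
    nv <- length(pos1)
    if (is.null(freq_spectrum)) {
      freq_spectrum <- seq_len(n_haplotypes - 1L) / n_haplotypes
    }
    if (nv > 0L) {
      ref <- substring(genome$sequence, pos1, pos1)
      alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                    character(1), USE.NAMES = FALSE)
      freq <- sample(freq_spectrum, nv, replace = TRUE)
      n_carriers <- pmax(1L, pmin(n_haplotypes,
                                  as.integer(round(freq * n_haplotypes))))
      carriers <- lapply(n_carriers, function(k) sample(n_haplotypes, k))
    } else {
      ref <- alt <- character(0)
      freq <- numeric(0)
      n_carriers <- integer(0)
      carriers <- list()
    }

    variants <- data.frame(
      pos = pos1 - 1L, ref = ref, alt = alt,
      class = classes[pos1],
      category = unname(cat_of_gene[gene_of[pos1]]),
      freq = n_carriers / n_haplotypes, n_carriers = n_carriers,
      stringsAsFactors = FALSE
    )
    hap_variants <- lapply(seq_len(n_haplotypes), function(h) {
      which(vapply(carriers, function(cs) h %in% cs, logical(1)))
    })
    fourfold_total <- length(fourfold_pos)
    onefold_total <- length(onefold_pos)
    n_n <- length(n_pos)
    realized <- list(
      ssnp_count = n_s, nsnp_count = n_n,
      ssnp_per_kb = n_s / (len / 1000), nsnp_per_kb = n_n / (len / 1000),
      fourfold_sites = fourfold_total, onefold_sites = onefold_total,
      true_pnps = if (n_s > 0) (n_n / onefold_total) / (n_s / fourfold_total)
      else NA_real_
    )
    structure(list(reference = genome, variants = variants,
                   carriers = carriers, haplotype_variants = hap_variants,
                   n_haplotypes = n_haplotypes, realized = realized),
              class = "haplotype_population")
  })
}

#' @export
print.haplotype_population <- function(x, ...) {
  cat(sprintf(paste0("<haplotype_population> %d haplotypes, %d variants ",
                     "(%d sSNP, %d nSNP), true pN/pS = %.4g\n"),
              x$n_haplotypes, nrow(x$variants), x$realized$ssnp_count,
              x$realized$nsnp_count, x$realized$true_pnps))
  invisible(x)
}

#' Reconstruct the full sequence of one haplotype
#'
#' @param population A [simulate_population()] result.
#' @param haplotype Haplotype index in `1:n_haplotypes`.
#' @return Character string: the reference with that haplotype's variant
#'   alleles applied.
#' @export
haplotype_sequence <- function(population, haplotype) {
  stopifnot(inherits(population, "haplotype_population"))
  seq <- population$reference$sequence
  idx <- population$haplotype_variants[[haplotype]]
  if (length(idx) > 0L) {
    ints <- utf8ToInt(seq)
    ints[population$variants$pos[idx] + 1L] <-
      utf8ToInt(paste(population$variants$alt[idx], collapse = ""))
    seq <- intToUtf8(ints)
  }
  seq
}

#' Count sites at which two haplotypes differ
#'
#' @param population A [simulate_population()] result.
#' @param i,j Haplotype indices.
#' @return Integer count of differing sites (symmetric difference of the
#'   two variant sets).
#' @export
haplotype_divergence <- function(population, i, j) {
  a <- population$haplotype_variants[[i]]
  b <- population$haplotype_variants[[j]]
  length(setdiff(a, b)) + length(setdiff(b, a))
}
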