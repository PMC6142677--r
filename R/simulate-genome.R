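#' Default functional-category weights for synthetic genomes
#'
#' Ten categories mirroring the functional classes commonly annotated on
#' small archaeal symbiont genomes, including the hypothetical
#' surface-exposed class that carries per-residue region labels.
#'
#' @return Named numeric vector of sampling weights.
#' @export
default_category_weights <- function() {
  c("Translation and ribosome" = 2,
    "DNA replication and repair" = 1.5,
    "RNA processing" = 1,
    "Transcription" = 1,
    "Protein modification" = 1,
    "Motility and attachment" = 1,
    "Energy metabolism" = 1,
    "Carbohydrate metabolism" = 0.5,
    "Hypothetical" = 2,
    "Hypothetical external" = 1.5)
}

#' Generate a synthetic annotated genome
#'
#' Emulates a compact archaeal-like genome: non-overlapping protein-coding
#' genes on both strands at high coding density, separated by short
#' intergenic stretches. Every gene starts with ATG, ends with a stop codon,
#' and contains no internal stops under translation table 11. Genes of the
#' categories in `region_label_categories` carry per-residue region labels
#' with an N-terminal transmembrane run (residues 5-23), internal before it
#' and external after it.
#'
#' @param seed Integer seed; same seed, same genome.
#' @param length Genome length in bp (>= 3000).
#' @param gene_fraction Target fraction of the genome that is coding, in
#'   (0, 1].
#' @param category_weights Named weights for sampling gene categories.
#' @param gene_length_range Range of gene lengths in codons (including the
#'   stop codon).
#' @param region_label_categories Categories whose genes get per-residue
#'   region labels.
#' @return An [annotated_genome()].
#' @export
make_genome <- function(seed, length, gene_fraction = 0.85,
                        category_weights = default_category_weights(),
                        gene_length_range = c(100L, 500L),
                        region_label_categories = "Hypothetical external") {
  stopifnot(length >= 3000L, gene_fraction >= 0, gene_fraction <= 1)
  with_seed(seed, {
    target_coding <- round(gene_fraction * length)
    # feasibility: even the fewest, longest genes need one gap each
    n_min <- ceiling(target_coding / (3 * gene_length_range[2]))
    if (target_coding + n_min + 1 > length) {
      stop("infeasible packing: gene_fraction ", gene_fraction,
           " too high for genome length ", length)
    }
    gene_lens <- integer(0)
    while (sum(gene_lens) < target_coding) {
      gene_lens <- c(gene_lens, 3L * sample(gene_length_range[1]:
                                              gene_length_range[2], 1L))
    }
    if (length(gene_lens) > 0L && sum(gene_lens) > target_coding) {
      # trim the last gene so realized coding stays close to the target
      excess <- sum(gene_lens) - target_coding
      n <- length(gene_lens)
      gene_lens[n] <- gene_lens[n] - 3L * (excess %/% 3L)
      if (gene_lens[n] < 3L * gene_length_range[1]) {
        gene_lens <- gene_lens[-n]
      }
    }
    ngenes <- length(gene_lens)
    gap_total <- length - sum(gene_lens)
    if (gap_total < ngenes + 1L) {
      stop("infeasible packing: gene_fraction ", gene_fraction,
           " too high for genome length ", length)
    }
    # partition the intergenic budget into ngenes + 1 gaps, each >= 1
    if (ngenes > 0L) {
      cuts <- sort(sample(gap_total - 1L, ngenes))
      gaps <- diff(c(0L, cuts, gap_total))
    } else {
      gaps <- gap_total
    }

    gc <- genetic_code_11()
    stops <- names(gc)[gc == "*"]
    sense <- setdiff(names(gc), stops)
    gene_seq <- function(len) {
      ncod <- len %/% 3L
      body <- sample(sense, ncod - 2L, replace = TRUE)
      paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
    }

    categories <- if (ngenes > 0L) {
      sample(names(category_weights), ngenes, replace = TRUE,
             prob = category_weights)
    } else character(0)
    strands <- if (ngenes > 0L) sample(c("+", "-"), ngenes, replace = TRUE)
    else character(0)

    pieces <- character(2L * ngenes + 1L)
    starts <- integer(ngenes)
    pos <- 0L
    for (i in seq_len(ngenes)) {
      pieces[2L * i - 1L] <- paste(sample(DNA_BASES, gaps[i], replace = TRUE),
                                   collapse = "")
      pos <- pos + gaps[i]
      starts[i] <- pos
      gs <- gene_seq(gene_lens[i])
      if (strands[i] == "-") gs <- revcomp(gs)
      pieces[2L * i] <- gs
      pos <- pos + gene_lens[i]
    }
    pieces[2L * ngenes + 1L] <-
      paste(sample(DNA_BASES, gaps[ngenes + 1L], replace = TRUE),
            collapse = "")
    sequence <- paste(pieces, collapse = "")

    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(ngenes)),
      start = starts, end = starts + gene_lens,
      strand = strands, category = categories,
      stringsAsFactors = FALSE
    )
    genes$regions <- lapply(seq_len(ngenes), function(i) {
      if (!categories[i] %in% region_label_categories) return(NULL)
      nres <- gene_lens[i] %/% 3L
      lab <- rep("external", nres)
      lab[1:min(4L, nres)] <- "internal"
      if (nres >= 5L) lab[5L:min(23L, nres)] <- "transmembrane"
      lab
    })
    annotated_genome(paste0("synth_", seed), sequence, genes)
  })
}
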