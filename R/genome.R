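#' Annotated genomes
#'
#' An annotated genome couples a reference sequence with its gene records.
#' All coordinates are 0-based half-open; conversions from 1-based formats
#' (GFF3, SAM) happen only at file boundaries.
#'
#' @param genome_id Genome identifier.
#' @param sequence Reference sequence (string over A/C/G/T; IUPAC ambiguity
#'   codes tolerated on input, excluded from SNP calling downstream).
#' @param genes A `data.frame` with columns `gene_id`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`), `category`, and optionally a
#'   list-column `regions` of per-residue labels
#'   (`internal`/`external`/`transmembrane`).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, sequence, genes = NULL) {
  sequence <- toupper(as.character(sequence))
  len <- nchar(sequence)
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        category = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "start", "end", "strand", "category") %in%
                  names(genes)))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$end <= genes$start)) stop("gene with end <= start")
  if (any(genes$start < 0L) || any(genes$end > len)) {
    stop("gene interval outside [0, genome length)")
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("unknown gene strand")
  if (nrow(genes) > 1L) {
    o <- order(genes$start)
    if (any(genes$start[o][-1L] < genes$end[o][-nrow(genes)])) {
      warning("overlapping genes on genome ", genome_id,
              "; first containing gene used for site classification")
    }
  }
  if ("regions" %in% names(genes)) {
    nres <- (genes$end - genes$start) %/% 3L
    has <- !vapply(genes$regions, is.null, logical(1))
    badlen <- has & lengths(genes$regions) != nres
    if (any(badlen)) stop("regions length must equal (end - start) / 3")
  }
  structure(list(genome_id = genome_id, sequence = sequence, genes = genes),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d bp, %d genes\n", x$genome_id,
              nchar(x$sequence), nrow(x$genes)))
  invisible(x)
}

#' @export
length.annotated_genome <- function(x) nchar(x$sequence)

revcomp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", s))))
  }, character(1), USE.NAMES = FALSE)
}

# Genetic code, translation table 11 (bacterial/archaeal).
genetic_code_11 <- function() Biostrings::getGeneticCode("11")

translate_cds <- function(seq) {
  gc <- genetic_code_11()
  codons <- substring(seq, seq(1L, nchar(seq) - 2L, 3L),
                      seq(3L, nchar(seq), 3L))
  paste(gc[codons], collapse = "")
}

# Degeneracy class of every codon x position: "fourfold" if all three
# alternative bases at that position leave the amino acid unchanged,
# "onefold" if all three change it (stop counts as a change), otherwise
# "other_coding". Precomputed once per session.
degeneracy_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- genetic_code_11()
    codons <- names(gc)
    tab <- matrix(NA_character_, nrow = 64L, ncol = 3L,
                  dimnames = list(codons, NULL))
    for (cod in codons) {
      aa <- gc[[cod]]
      for (p in 1:3) {
        alts <- DNA_BASES[DNA_BASES != substr(cod, p, p)]
        mut <- vapply(alts, function(b) {
          m <- cod
          substr(m, p, p) <- b
          gc[[m]]
        }, character(1))
        same <- sum(mut == aa)
        tab[cod, p] <- if (same == 3L) "fourfold"
        else if (same == 0L) "onefold" else "other_coding"
      }
    }
    cache <<- tab
    tab
  }
})

#' Classify every genome position by codon degeneracy
#'
#' Positions inside coding genes are classified under translation table 11,
#' strand-aware, as `fourfold` (all three substitutions synonymous),
#' `onefold` (all three non-synonymous; stop counts as a change) or
#' `other_coding`; positions outside genes are `intergenic`. Genes whose
#' length is not a multiple of 3 are classified `other_coding` throughout,
#' with a warning, as are codons containing ambiguous bases. Where genes
#' overlap, the first containing gene (by start) wins.
#'
#' @param genome An [annotated_genome()].
#' @return Character vector of classes, one per genome position, with the
#'   assigning gene id in attribute `gene_id`.
#' @export
classify_genome_sites <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  len <- nchar(genome$sequence)
  classes <- rep("intergenic", len)
  gene_ids <- rep(NA_character_, len)
  tab <- degeneracy_table()
  genes <- genome$genes
  if (nrow(genes) == 0L) {
    return(structure(classes, gene_id = gene_ids))
  }
  for (i in order(genes$start)) {
    g <- genes[i, ]
    span <- (g$start + 1L):g$end # 1-based indices into sequence
    unassigned <- is.na(gene_ids[span])
    if (!any(unassigned)) next
    glen <- g$end - g$start
    if (glen %% 3L != 0L) {
      warning("gene ", g$gene_id, " length not a multiple of 3; ",
              "classified other_coding")
      cls <- rep("other_coding", glen)
    } else {
      gseq <- substr(genome$sequence, g$start + 1L, g$end)
      if (g$strand == "-") gseq <- revcomp(gseq)
      codons <- substring(gseq, seq(1L, glen - 2L, 3L), seq(3L, glen, 3L))
      idx <- match(codons, rownames(tab))
      percodon <- matrix("other_coding", nrow = length(codons), ncol = 3L)
      ok <- !is.na(idx)
      percodon[ok, ] <- tab[idx[ok], , drop = FALSE]
      cls <- as.vector(t(percodon)) # coding-strand order
      if (g$strand == "-") cls <- rev(cls)
    }
    classes[span][unassigned] <- cls[unassigned]
    gene_ids[span][unassigned] <- g$gene_id
  }
  structure(classes, gene_id = gene_ids)
}

#' Degeneracy class of a single genome position
#'
#' @param genome An [annotated_genome()].
#' @param pos 0-based position (vectorized).
#' @return Character vector over `fourfold`, `onefold`, `other_coding`,
#'   `intergenic`.
#' @export
site_degeneracy <- function(genome, pos) {
  classes <- classify_genome_sites(genome)
  stopifnot(all(pos >= 0L), all(pos < length(classes)))
  as.character(classes[pos + 1L])
}
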