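#' Describe a SAG sequencing scenario
#'
#' A scenario bundles everything needed to emit one SAG read set: which
#' haplotypes were in the sorted particle and in what proportions, the
#' target fold-coverage, the per-base substitution error rate, and the
#' MDA-style amplification bias (log-normal window-level depth
#' multipliers). `k = 1` with no host is a "single-sort clonal" scenario.
#'
#' @param scenario_id Identifier used as read-name prefix.
#' @param cell_haplotype_ids Haplotype indices of the cells in the sort
#'   (length k >= 1).
#' @param mixture_weights Read proportions per cell; must sum to 1.
#' @param coverage_mean Mean fold-coverage.
#' @param error_rate Per-base substitution error probability.
#' @param mda_bias Log-normal sigma of window-level amplification factors
#'   (0 = uniform coverage).
#' @param window Window size in bp for the amplification bias.
#' @param read_length Read length in nt.
#' @param qual_correct Phred quality of correctly sequenced bases.
#' @param err_qual Range (lo, hi) of Phred qualities for error bases; low
#'   by default so the base-quality filter removes most simulated errors.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `sag_scenario`.
#' @export
sag_scenario <- function(scenario_id, cell_haplotype_ids,
                         mixture_weights = NULL, coverage_mean = 50,
                         error_rate = 0.002, mda_bias = 1.0, window = 1000L,
                         read_length = 150L, qual_correct = 40L,
                         err_qual = c(2L, 20L), seed = NULL) {
  k <- length(cell_haplotype_ids)
  stopifnot(k >= 1L)
  if (is.null(mixture_weights)) mixture_weights <- rep(1 / k, k)
  if (abs(sum(mixture_weights) - 1) > 1e-9) {
    stop("mixture_weights must sum to 1")
  }
  if (coverage_mean <= 0) stop("coverage_mean must be positive")
  structure(list(scenario_id = scenario_id,
                 cell_haplotype_ids = cell_haplotype_ids,
                 mixture_weights = mixture_weights,
                 coverage_mean = coverage_mean, error_rate = error_rate,
                 mda_bias = mda_bias, window = as.integer(window),
                 read_length = as.integer(read_length),
                 qual_correct = as.integer(qual_correct),
                 err_qual = as.integer(err_qual), seed = seed),
            class = "sag_scenario")
}

# Draw 0-based read start positions with MDA-style window-level bias.
draw_read_starts <- function(n_reads, genome_len, read_length, window,
                             mda_bias) {
  max_start <- genome_len - read_length
  nw <- ceiling(genome_len / window)
  w <- if (mda_bias > 0) stats::rlnorm(nw, 0, mda_bias) else rep(1, nw)
  win <- sample.int(nw, n_reads, replace = TRUE, prob = w)
  starts <- (win - 1L) * window +
    floor(stats::runif(n_reads) * window)
  as.integer(pmin(starts, max_start))
}

#' Simulate a SAG read set from a haplotype population
#'
#' Emits error-perturbed reads from the scenario's cell haplotypes in
#' proportion to the mixture weights, with log-normal window-level depth
#' bias emulating MDA amplification. Reads carry their true positions (the
#' package does not implement a mapper; mapping noise enters via the
#' identity/quality filters on the perturbed records). The NM tag is the
#' read's edit distance to the *reference*, so haplotype variants and
#' sequencing errors both count, exactly as after real read mapping.
#'
#' @param scenario A [sag_scenario()].
#' @param population A [simulate_population()] result.
#' @param n_reads Override the read count implied by `coverage_mean`.
#' @return A list with `alignments` (an [alignment_table()]) and `truth`
#'   (data.frame: `read_id`, `haplotype`, `pos`).
#' @export
simulate_sag_reads <- function(scenario, population, n_reads = NULL) {
  stopifnot(inherits(scenario, "sag_scenario"),
            inherits(population, "haplotype_population"))
  if (!all(scenario$cell_haplotype_ids %in%
             seq_len(population$n_haplotypes))) {
    stop("scenario haplotype ids not present in population")
  }
  with_seed(scenario$seed, {
    ref <- population$reference$sequence
    len <- nchar(ref)
    rl <- scenario$read_length
    if (is.null(n_reads)) {
      n_reads <- round(scenario$coverage_mean * len / rl)
    }
    starts <- draw_read_starts(n_reads, len, rl, scenario$window,
                               scenario$mda_bias)
    k <- length(scenario$cell_haplotype_ids)
    cell <- if (k == 1L) rep(1L, n_reads) else {
      sample.int(k, n_reads, replace = TRUE, prob = scenario$mixture_weights)
    }
    # emit reads grouped by cell and sorted by position (cache-friendly)
    parts <- vector("list", k)
    cells_out <- integer(0)
    starts_out <- integer(0)
    for (ci in seq_len(k)) {
      st <- sort(starts[cell == ci])
      if (length(st) == 0L) next
      hap <- haplotype_sequence(population, scenario$cell_haplotype_ids[ci])
      parts[[ci]] <- cpp_make_reads(hap, ref, st, rl, scenario$error_rate,
                                    scenario$qual_correct,
                                    scenario$err_qual[1],
                                    scenario$err_qual[2])
      cells_out <- c(cells_out, rep(ci, length(st)))
      starts_out <- c(starts_out, st)
    }
    parts <- parts[!vapply(parts, is.null, logical(1))]
    seqs <- unlist(lapply(parts, `[[`, "seq"), use.names = FALSE)
    quals <- unlist(lapply(parts, `[[`, "qual"), use.names = FALSE)
    nm <- unlist(lapply(parts, `[[`, "nm"), use.names = FALSE)
    read_id <- paste0(scenario$scenario_id, "_r", seq_len(n_reads))
    aln <- new_alignment_table(read_id, population$reference$genome_id,
                               starts_out, seqs, quals, mapq = 60L, nm = nm,
                               cigar = paste0(rl, "M"))
    truth <- data.frame(read_id = read_id,
                        haplotype = scenario$cell_haplotype_ids[cells_out],
                        pos = starts_out, stringsAsFactors = FALSE)
    list(alignments = aln, truth = truth)
  })
}

#' Shred contigs into synthetic error-free read pairs
#'
#' Emulates assembly-shredding read simulation: paired 150 nt reads at
#' uniform positions, insert sizes uniform in `insert_range`, no sequencing
#' error, uniform high base quality, total read bases approximately
#' `coverage` times the total contig length. Contigs shorter than the
#' maximum insert are rejected; contigs shorter than the read length are
#' skipped with a warning.
#'
#' @param contigs Named character vector of contig sequences.
#' @param coverage Target fold-coverage.
#' @param insert_range Insert size range in nt (min, max).
#' @param read_length Read length in nt.
#' @param seed Integer seed or `NULL`.
#' @return An [alignment_table()] over the contigs.
#' @export
shred_contigs <- function(contigs, coverage = 20, insert_range = c(180L, 400L),
                          read_length = 150L, seed = NULL) {
  contigs <- unlist(contigs)
  stopifnot(!is.null(names(contigs)))
  with_seed(seed, {
    out <- vector("list", length(contigs))
    for (i in seq_along(contigs)) {
      cname <- names(contigs)[i]
      cseq <- toupper(contigs[[i]])
      clen <- nchar(cseq)
      if (clen < read_length) {
        warning("contig ", cname, " shorter than read length; skipped")
        next
      }
      if (clen < insert_range[2]) {
        stop("contig ", cname, " shorter than maximum insert size ",
             insert_range[2])
      }
      npairs <- ceiling(coverage * clen / (2 * read_length))
      insert <- sample(insert_range[1]:insert_range[2], npairs,
                       replace = TRUE)
      s1 <- floor(stats::runif(npairs) * (clen - insert + 1L))
      s2 <- s1 + insert - read_length
      qual <- strrep(rawToChar(as.raw(33L + 40L)), read_length)
      id <- paste0(cname, "_p", seq_len(npairs))
      out[[i]] <- alignment_table(
        read_id = c(paste0(id, "/1"), paste0(id, "/2")),
        target_id = cname,
        pos = c(s1, s2),
        seq = substring(cseq, c(s1, s2) + 1L, c(s1, s2) + read_length),
        qual = qual, mapq = 60L, nm = 0L,
        cigar = paste0(read_length, "M")
      )
    }
    out <- do.call(rbind, out)
    if (is.null(out)) {
      out <- alignment_table(character(), character(), integer(),
                             character(), character(), integer(), integer(),
                             character())
    }
    rownames(out) <- NULL
    class(out) <- c("alignment_table", "data.frame")
    out
  })
}

#' Simulate a co-sorted symbiont + host read mixture
#'
#' Produces a two-target alignment table exactly as if a co-sorted SAG had
#' been mapped against both the symbiont and host genome bins: each read is
#' a host read with probability `host_read_fraction`, host reads are drawn
#' clonally from the host genome, symbiont reads follow the scenario.
#'
#' @param symbiont_scenario A [sag_scenario()] for the symbiont partition.
#' @param population Symbiont [simulate_population()].
#' @param host_genome Host [annotated_genome()].
#' @param host_read_fraction Fraction of reads originating from the host,
#'   in (0, 1).
#' @param seed Integer seed or `NULL`.
#' @return A list with `alignments` (two-target [alignment_table()]) and
#'   `truth` (per-read target, haplotype, position).
#' @export
simulate_cosort <- function(symbiont_scenario, population, host_genome,
                            host_read_fraction, seed = NULL) {
  stopifnot(host_read_fraction > 0, host_read_fraction < 1,
            inherits(host_genome, "annotated_genome"))
  with_seed(seed, {
    sc <- symbiont_scenario
    len_s <- nchar(population$reference$sequence)
    n_sym_nominal <- round(sc$coverage_mean * len_s / sc$read_length)
    n_total <- round(n_sym_nominal / (1 - host_read_fraction))
    n_host <- stats::rbinom(1L, n_total, host_read_fraction)
    n_sym <- n_total - n_host

    sym <- simulate_sag_reads(sc, population, n_reads = n_sym)

    host_len <- nchar(host_genome$sequence)
    rl <- sc$read_length
    hstarts <- draw_read_starts(n_host, host_len, rl, sc$window, sc$mda_bias)
    hr <- cpp_make_reads(host_genome$sequence, host_genome$sequence, hstarts,
                         rl, sc$error_rate, sc$qual_correct, sc$err_qual[1],
                         sc$err_qual[2])
    host_ids <- paste0(sc$scenario_id, "_h", seq_len(n_host))
    host_aln <- alignment_table(host_ids, host_genome$genome_id, hstarts,
                                hr$seq, hr$qual, mapq = 60L, nm = hr$nm,
                                cigar = paste0(rl, "M"))
    aln <- rbind(sym$alignments, host_aln)
    rownames(aln) <- NULL
    class(aln) <- c("alignment_table", "data.frame")
    truth <- rbind(
      data.frame(read_id = sym$truth$read_id,
                 target_id = population$reference$genome_id,
                 haplotype = sym$truth$haplotype, pos = sym$truth$pos,
                 stringsAsFactors = FALSE),
      data.frame(read_id = host_ids, target_id = host_genome$genome_id,
                 haplotype = NA_integer_, pos = hstarts,
                 stringsAsFactors = FALSE)
    )
    list(alignments = aln, truth = truth)
  })
}
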