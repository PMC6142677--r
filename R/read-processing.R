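#' Site counts
#'
#' Per-position A/C/G/T counts for one target: the unit SNP calling and
#' consensus calling act on. Flags: `covered` (usable), `dropped_low_depth`
#' (insufficient depth after downsampling; excluded from all denominators)
#' and `reference_N` (ambiguous reference base; always excluded).
#'
#' @param target_id Target identifier.
#' @param counts Integer matrix, positions x 4 (columns A, C, G, T).
#' @param ref Reference sequence string for the target.
#' @param flag Per-position flag vector; defaults to `covered`.
#' @param target_depth Uniform depth after downsampling/pooling, if any.
#' @return An object of class `site_counts`.
#' @export
site_counts <- function(target_id, counts, ref, flag = NULL,
                        target_depth = NULL) {
  stopifnot(is.matrix(counts), ncol(counts) == 4L,
            nrow(counts) == nchar(ref))
  colnames(counts) <- DNA_BASES
  refbase <- intToUtf8(utf8ToInt(toupper(ref)), multiple = TRUE)
  if (is.null(flag)) flag <- rep("covered", nrow(counts))
  flag[!refbase %in% DNA_BASES] <- "reference_N"
  structure(list(target_id = target_id, counts = counts, ref = ref,
                 refbase = refbase, flag = flag,
                 target_depth = target_depth),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  d <- rowSums(x$counts)
  cat(sprintf(paste0("<site_counts> %s: %d positions, %d covered, ",
                     "mean depth %.1f\n"), x$target_id, nrow(x$counts),
              sum(x$flag == "covered" & d > 0), mean(d)))
  invisible(x)
}

site_depth <- function(counts) rowSums(counts$counts)

#' Filter alignment records
#'
#' Discards records with identity below `min_identity` (identity =
#' 1 - NM / reference-consuming CIGAR length), mean base quality below
#' `min_mean_read_q`, or mapping quality below `min_mapq`. All thresholds
#' follow "discard if strictly less than" semantics, so records exactly at
#' a threshold are kept. Per-filter removal counts are attached as
#' attribute `filter_log`.
#'
#' @param aln An [alignment_table()].
#' @param min_identity Minimum alignment identity (fraction).
#' @param min_mean_read_q Minimum arithmetic mean Phred score per read.
#' @param min_mapq Minimum mapping quality.
#' @return The filtered [alignment_table()].
#' @export
filter_alignments <- function(aln, min_identity = 0.95,
                              min_mean_read_q = 30, min_mapq = 20) {
  stopifnot(inherits(aln, "alignment_table"))
  if (anyNA(aln$nm)) stop("NM required on every record")
  if (nrow(aln) == 0L) return(aln)
  alen <- cigar_ref_length(aln$cigar)
  identity <- 1 - aln$nm / alen
  meanq <- cpp_mean_qual(aln$qual)
  keep_id <- identity >= min_identity
  keep_q <- meanq >= min_mean_read_q
  keep_mq <- aln$mapq >= min_mapq
  keep <- keep_id & keep_q & keep_mq
  cols <- lapply(unclass(aln), `[`, keep)
  out <- structure(cols, class = c("alignment_table", "data.frame"),
                   row.names = .set_row_names(sum(keep)))
  attr(out, "filter_log") <- c(low_identity = sum(!keep_id),
                               low_read_quality = sum(!keep_q),
                               low_mapq = sum(!keep_mq))
  out
}

#' Quality-aware pileup
#'
#' Counts, at every reference position, the read bases with Phred quality
#' at or above `min_base_q` (bases strictly below are excluded). CIGAR
#' semantics: M/=/X consume read and reference, I and S consume read only
#' (inserted/clipped bases are never counted), D consumes reference only.
#'
#' @param aln A filtered [alignment_table()] on a single target.
#' @param reference The target [annotated_genome()], or a single named
#'   character sequence.
#' @param min_base_q Minimum base quality.
#' @return A [site_counts()] object.
#' @export
pileup <- function(aln, reference, min_base_q = 30) {
  stopifnot(inherits(aln, "alignment_table"))
  if (inherits(reference, "annotated_genome")) {
    target_id <- reference$genome_id
    ref <- reference$sequence
  } else {
    stopifnot(length(reference) == 1L, !is.null(names(reference)))
    target_id <- names(reference)
    ref <- toupper(unname(reference))
  }
  if (nrow(aln) > 0L && !all(aln$target_id == target_id)) {
    stop("alignment table contains records for other targets than ",
         target_id)
  }
  counts <- cpp_pileup(aln$pos, aln$seq, aln$qual, aln$cigar, aln$read_id,
                       nchar(ref), as.integer(min_base_q))
  site_counts(target_id, counts, ref)
}

#' Downsample site counts to a fixed per-site depth
#'
#' Positions with depth at or above `target_depth` are subsampled to
#' exactly `target_depth` base observations without replacement
#' (multivariate hypergeometric, so allele proportions are preserved in
#' expectation); positions below it are flagged `dropped_low_depth` and
#' excluded from all downstream denominators.
#'
#' @param counts A [site_counts()] object.
#' @param target_depth Depth to downsample to (>= 1).
#' @param seed Integer seed or `NULL`.
#' @return A [site_counts()] object with uniform depth on covered sites.
#' @export
downsample_sites <- function(counts, target_depth = 50L, seed = NULL) {
  stopifnot(inherits(counts, "site_counts"), target_depth >= 1L)
  with_seed(seed, {
    m <- counts$counts
    d <- rowSums(m)
    out <- matrix(0L, nrow = nrow(m), ncol = 4L,
                  dimnames = list(NULL, DNA_BASES))
    flag <- counts$flag
    low <- d < target_depth
    flag[low & flag != "reference_N"] <- "dropped_low_depth"
    take <- which(!low)
    if (length(take) > 0L) {
      sub <- m[take, , drop = FALSE]
      dep <- d[take]
      na <- rhyper_safe(sub[, 1], dep - sub[, 1], target_depth)
      rem <- target_depth - na
      nc <- rhyper_safe(sub[, 2], dep - sub[, 1] - sub[, 2], rem)
      rem <- rem - nc
      ng <- rhyper_safe(sub[, 3], dep - sub[, 1] - sub[, 2] - sub[, 3], rem)
      nt <- rem - ng
      out[take, ] <- cbind(na, nc, ng, nt)
    }
    site_counts(counts$target_id, out, counts$ref, flag,
                target_depth = as.integer(target_depth))
  })
}

# Vectorized hypergeometric draw tolerant of k = 0 and m + n = 0.
rhyper_safe <- function(m, n, k) {
  res <- integer(length(m))
  ok <- k > 0L & (m + n) > 0L
  kk <- pmin(k, m + n)[ok]
  res[ok] <- stats::rhyper(sum(ok), m[ok], n[ok], kk)
  res
}

#' Pool site counts from several SAGs with equal per-SAG contribution
#'
#' Emulates multiple distinct cells attached to one host: per position,
#' each of the k SAGs contributes exactly `floor(target_depth / k)` reads,
#' sampled without replacement; a position is eligible only if every SAG
#' has at least that depth there. Pre-downsampling counts are expected.
#'
#' @param counts_list List of [site_counts()] on the same target.
#' @param target_depth Total pooled depth budget.
#' @param seed Integer seed or `NULL`.
#' @return A [site_counts()] object with uniform depth
#'   `k * floor(target_depth / k)` on covered sites.
#' @export
pool_counts <- function(counts_list, target_depth = 50L, seed = NULL) {
  k <- length(counts_list)
  stopifnot(k >= 1L)
  if (k > target_depth) stop("more SAGs (", k, ") than target depth")
  tid <- unique(vapply(counts_list, `[[`, character(1), "target_id"))
  if (length(tid) != 1L) stop("all site counts must be on the same target")
  s <- target_depth %/% k
  with_seed(seed, {
    downs <- lapply(counts_list, downsample_sites, target_depth = s)
    pooled <- Reduce(`+`, lapply(downs, `[[`, "counts"))
    eligible <- Reduce(`&`, lapply(downs, function(x) x$flag == "covered"))
    flag <- ifelse(eligible, "covered", "dropped_low_depth")
    pooled[!eligible, ] <- 0L
    site_counts(tid, pooled, counts_list[[1]]$ref, flag,
                target_depth = as.integer(k * s))
  })
}
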