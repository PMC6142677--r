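#' Alignment tables
#'
#' An alignment table is the package's internal representation of mapped
#' reads: one row per mapped record with 0-based leftmost position, read
#' sequence, per-base Phred qualities (ASCII offset 33), mapping quality,
#' edit distance (SAM NM tag) and CIGAR. It is the unit the alignment
#' filters act on.
#'
#' @param read_id,target_id,pos,seq,qual,mapq,nm,cigar,flag Per-record
#'   vectors; `pos` is 0-based.
#' @return A `data.frame` with class `alignment_table`.
#' @export
alignment_table <- function(read_id, target_id, pos, seq, qual, mapq, nm,
                            cigar, flag = 0L) {
  df <- data.frame(
    read_id = as.character(read_id), target_id = as.character(target_id),
    pos = as.integer(pos), seq = toupper(as.character(seq)),
    qual = as.character(qual), mapq = as.integer(mapq), nm = as.integer(nm),
    cigar = as.character(cigar), flag = as.integer(flag),
    stringsAsFactors = FALSE
  )
  bad <- nchar(df$seq) != nchar(df$qual)
  if (any(bad)) {
    stop("seq/qual length mismatch for read(s): ",
         paste(utils::head(df$read_id[bad], 5), collapse = ", "))
  }
  class(df) <- c("alignment_table", "data.frame")
  df
}

# Internal fast constructor: callers guarantee equal-length seq/qual and
# consistent field lengths (used on simulator output).
new_alignment_table <- function(read_id, target_id, pos, seq, qual, mapq,
                                nm, cigar, flag = 0L) {
  n <- length(pos)
  structure(
    list(read_id = read_id, target_id = rep_len(target_id, n),
         pos = as.integer(pos), seq = seq, qual = rep_len(qual, n),
         mapq = rep_len(as.integer(mapq), n), nm = as.integer(nm),
         cigar = rep_len(cigar, n), flag = rep_len(as.integer(flag), n)),
    class = c("alignment_table", "data.frame"),
    row.names = .set_row_names(n)
  )
}

SUPPORTED_CIGAR_OPS <- c("M", "I", "D", "S", "=", "X")

check_cigar_ops <- function(cigar, read_id) {
  ops <- gsub("[0-9]", "", cigar)
  bad <- vapply(strsplit(ops, ""), function(x) any(!x %in% SUPPORTED_CIGAR_OPS),
                logical(1))
  if (any(bad)) {
    stop("unsupported CIGAR operation(s) in read(s): ",
         paste(utils::head(read_id[bad], 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a SAM file into an alignment table
#'
#' Parses the 11 mandatory SAM columns plus the required `NM:i` tag.
#' Positions are converted from SAM's 1-based to the package's 0-based
#' convention. Unmapped records (FLAG 0x4) and secondary/supplementary
#' records (FLAG 0x100/0x800) are dropped. Records without an NM tag are an
#' error: downstream identity filtering needs the edit distance.
#'
#' @param path Path to a plain-text SAM file.
#' @param target_ids Optional character vector; keep only records mapped to
#'   these targets.
#' @return An [alignment_table()].
#' @export
read_sam <- function(path, target_ids = NULL) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(alignment_table(character(), character(), integer(), character(),
                           character(), integer(), integer(), character(),
                           integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("SAM record with fewer than 11 mandatory columns at line(s): ",
         paste(utils::head(which(nf < 11L), 5), collapse = ", "))
  }
  col <- function(i) vapply(fields, `[`, character(1), i)
  flag <- as.integer(col(2))
  keep <- bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x100L) == 0L &
    bitwAnd(flag, 0x800L) == 0L
  fields <- fields[keep]
  flag <- flag[keep]
  if (length(fields) == 0L) {
    return(alignment_table(character(), character(), integer(), character(),
                           character(), integer(), integer(), character(),
                           integer()))
  }
  read_id <- col(1)
  target_id <- col(3)
  pos <- as.integer(col(4)) - 1L
  mapq <- as.integer(col(5))
  cigar <- col(6)
  seq <- toupper(col(10))
  qual <- col(11)
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag) == 0L) NA_integer_ else as.integer(sub("^NM:i:", "", tag[1]))
  }, integer(1))
  if (anyNA(nm)) {
    stop("SAM record(s) lacking NM:i tag: ",
         paste(utils::head(read_id[is.na(nm)], 5), collapse = ", "))
  }
  check_cigar_ops(cigar, read_id)
  aln <- alignment_table(read_id, target_id, pos, seq, qual, mapq, nm, cigar,
                         flag)
  if (!is.null(target_ids)) {
    aln <- aln[aln$target_id %in% target_ids, , drop = FALSE]
    rownames(aln) <- NULL
    class(aln) <- c("alignment_table", "data.frame")
  }
  aln
}

#' Write an alignment table as SAM
#'
#' Emits a minimal valid SAM file (header with `@SQ` lines, 11 mandatory
#' columns, `NM:i` tag) that [read_sam()] reads back losslessly.
#'
#' @param aln An [alignment_table()].
#' @param target_lengths Named integer vector of target sequence lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, target_lengths, path) {
  stopifnot(inherits(aln, "alignment_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (tid in names(target_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", tid,
                       as.integer(target_lengths[[tid]])), con)
  }
  if (nrow(aln) > 0L) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                       aln$read_id, aln$flag, aln$target_id, aln$pos + 1L,
                       aln$mapq, aln$cigar, aln$seq, aln$qual, aln$nm), con)
  }
  invisible(path)
}

# Reference-consuming length of each CIGAR string.
cigar_ref_length <- function(cigar) {
  cpp_cigar_ref_len(cigar)
}
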