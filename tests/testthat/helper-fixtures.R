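# Shared fixtures, all built in code.

# A tiny hand-made genome: 6 bp intergenic, one 15 bp plus-strand gene
# (ATG AAA CTT GGC TAA), 6 bp intergenic.
tiny_genome <- function() {
  annotated_genome(
    "tiny",
    paste0("ACACAC", "ATGAAACTTGGCTAA", "GTGTGT"),
    data.frame(gene_id = "g1", start = 6L, end = 21L, strand = "+",
               category = "Hypothetical", stringsAsFactors = FALSE)
  )
}

# Small synthetic genome for pipeline tests.
small_genome <- function(seed = 101, length = 12000) {
  make_genome(seed = seed, length = length, gene_fraction = 0.85)
}

# Single-read alignment table with controllable filter-relevant fields.
one_read <- function(pos = 0L, seq = strrep("A", 150), nm = 0L, mapq = 60L,
                     qual = strrep(rawToChar(as.raw(33 + 40)), nchar(seq)),
                     cigar = paste0(nchar(seq), "M"), target = "tiny",
                     read_id = "r1") {
  alignment_table(read_id, target, pos, seq, qual, mapq, nm, cigar)
}

qual_string <- function(phred) {
  rawToChar(as.raw(33L + as.integer(phred)))
}

# Seven-genome clade-evidence fixture: clade {A,B} seeded by 16S+ANI;
# clade {C,D} seeded by ANI+tree; E joins {C,D} by ANI extension (16S and
# tree missing); F is blocked by a conflict (16S PASS but ANI FAIL against
# A); G has no evidence at all.
clade_fixture <- function() {
  data.frame(
    id_a = c("A", "C", "C", "A"),
    id_b = c("B", "D", "E", "F"),
    s16 = c("PASS", NA, NA, "PASS"),
    ani = c("PASS", "PASS", "PASS", "FAIL"),
    tree = c(NA, "PASS", NA, NA),
    stringsAsFactors = FALSE
  )
}

# site_counts built directly from a count matrix.
counts_fixture <- function(mat, ref = strrep("A", nrow(mat)),
                           target = "t", flag = NULL, target_depth = NULL) {
  site_counts(target, mat, ref, flag = flag, target_depth = target_depth)
}
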