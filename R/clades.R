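#' Pairwise 16S rRNA identity over comparable columns
#'
#' Identity is computed over alignment columns where both sequences are
#' non-gap: matches / comparable columns x 100. Returns `NA` (MISSING
#' evidence) when no column is comparable.
#'
#' @param aligned_a,aligned_b Equal-length aligned sequences (gaps `-` or
#'   `.`).
#' @return Percent identity, or `NA_real_`.
#' @export
pairwise_16s_identity <- function(aligned_a, aligned_b) {
  a <- strsplit(toupper(aligned_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(aligned_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  gap <- c("-", ".")
  comparable <- !(a %in% gap) & !(b %in% gap)
  if (!any(comparable)) return(NA_real_)
  100 * sum(a[comparable] == b[comparable]) / sum(comparable)
}

# Locate a fragment in the subject by exact k-mer seeding; returns the
# subject window around the best-supported diagonal, or NULL.
seed_window <- function(fragment, subject_dna, seed_k = 16L, n_seeds = 12L,
                        pad = 60L) {
  flen <- nchar(fragment)
  offs <- unique(as.integer(round(seq(1L, flen - seed_k + 1L,
                                      length.out = n_seeds))))
  diags <- integer(0)
  for (o in offs) {
    seed <- substr(fragment, o, o + seed_k - 1L)
    if (grepl("[^ACGT]", seed)) next
    hits <- Biostrings::matchPattern(seed, subject_dna)
    st <- Biostrings::start(hits)
    if (length(st) > 0L && length(st) <= 10L) diags <- c(diags, st - o)
  }
  if (length(diags) == 0L) return(NULL)
  diag <- as.integer(names(sort(table(diags), decreasing = TRUE))[1])
  slen <- length(subject_dna)
  from <- max(1L, diag + 1L - pad)
  to <- min(slen, diag + flen + pad)
  list(from = from, to = to)
}

#' Average nucleotide identity, fragment-based (ANIb style)
#'
#' The query is cut into consecutive `fragment`-bp fragments (a trailing
#' partial fragment is dropped); each fragment is located in the subject
#' by exact 16-mer seeding and locally aligned (Smith-Waterman with
#' blastn-like scoring) within a banded window around the seeded diagonal.
#' Fragments are retained iff alignment identity >= `min_frag_identity`
#' and the alignment covers >= `min_frag_coverage` of the fragment. ANI is
#' the mean identity of retained fragments (x 100), the aligned length the
#' sum of retained alignment lengths; the result is symmetrized as the
#' mean of both directions. With no retained fragments the ANI is `NA`
#' (MISSING evidence), never a numeric 0.
#'
#' @param genome_a,genome_b Sequences (strings, or [annotated_genome()]).
#' @param fragment Fragment length in bp.
#' @param min_frag_identity Minimum alignment identity for retention.
#' @param min_frag_coverage Minimum fraction of the fragment covered by
#'   the alignment.
#' @return A list: `ani` (percent, `NA` if missing), `aligned_length`
#'   (bp, averaged over directions), `n_fragments_retained`.
#' @export
anib <- function(genome_a, genome_b, fragment = 1020L,
                 min_frag_identity = 0.30, min_frag_coverage = 0.70) {
  seq_a <- if (inherits(genome_a, "annotated_genome")) genome_a$sequence
  else toupper(as.character(genome_a))
  seq_b <- if (inherits(genome_b, "annotated_genome")) genome_b$sequence
  else toupper(as.character(genome_b))
  if (nchar(seq_a) < fragment || nchar(seq_b) < fragment) {
    stop("both genomes must be at least one fragment (", fragment, " bp) long")
  }
  d1 <- anib_one_direction(seq_a, seq_b, fragment, min_frag_identity,
                           min_frag_coverage)
  d2 <- anib_one_direction(seq_b, seq_a, fragment, min_frag_identity,
                           min_frag_coverage)
  if (is.na(d1$ani) || is.na(d2$ani)) {
    return(list(ani = NA_real_, aligned_length = 0L,
                n_fragments_retained = d1$n_retained + d2$n_retained))
  }
  list(ani = (d1$ani + d2$ani) / 2,
       aligned_length = as.integer(round((d1$aligned_length +
                                            d2$aligned_length) / 2)),
       n_fragments_retained = d1$n_retained + d2$n_retained)
}

anib_one_direction <- function(query, subject, fragment, min_frag_identity,
                               min_frag_coverage) {
  nfrag <- nchar(query) %/% fragment
  subject_dna <- Biostrings::DNAString(subject)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  ids <- numeric(0)
  alens <- integer(0)
  for (i in seq_len(nfrag)) {
    frag <- substr(query, (i - 1L) * fragment + 1L, i * fragment)
    win <- seed_window(frag, subject_dna)
    if (is.null(win)) next
    sub <- Biostrings::subseq(subject_dna, win$from, win$to)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(frag), sub, type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2
    )
    alen <- Biostrings::nchar(aln)
    identity <- Biostrings::nmatch(aln) / alen
    qcov <- Biostrings::width(Biostrings::pattern(aln)) / fragment
    if (identity >= min_frag_identity && qcov >= min_frag_coverage) {
      ids <- c(ids, identity)
      alens <- c(alens, alen)
    }
  }
  if (length(ids) == 0L) {
    return(list(ani = NA_real_, aligned_length = 0L, n_retained = 0L))
  }
  list(ani = 100 * mean(ids), aligned_length = sum(alens),
       n_retained = length(ids))
}

#' Tree criterion for clade membership
#'
#' `MISSING` (`NA`) if any member is absent from the tree. `PASS` if (a)
#' for a pair, each member is the other's nearest leaf by patristic
#' distance, or (b) the smallest monophyletic group containing all
#' members contains no non-members; otherwise `FAIL`. For trees without
#' branch lengths only the monophyly condition is evaluated.
#'
#' @param tree An [ape::phylo] tree with genome ids as tip labels.
#' @param member_ids Candidate clade member ids (>= 2).
#' @return `"PASS"`, `"FAIL"`, or `NA_character_` (missing).
#' @export
tree_criterion <- function(tree, member_ids) {
  stopifnot(length(member_ids) >= 2L)
  if (!all(member_ids %in% tree$tip.label)) return(NA_character_)
  # (b) smallest clade containing all members
  if (length(member_ids) == length(tree$tip.label)) {
    clade_tips <- tree$tip.label
  } else {
    mrca <- ape::getMRCA(tree, member_ids)
    clade_tips <- if (is.null(mrca)) tree$tip.label
    else ape::extract.clade(tree, mrca)$tip.label
  }
  if (all(clade_tips %in% member_ids)) return("PASS")
  # (a) mutual nearest neighbours, pairs only, needs branch lengths
  if (length(member_ids) == 2L && !is.null(tree$edge.length)) {
    dm <- ape::cophenetic.phylo(tree)
    a <- member_ids[1]
    b <- member_ids[2]
    nn <- function(x) {
      d <- dm[x, setdiff(colnames(dm), x)]
      names(d)[d == min(d)]
    }
    if (b %in% nn(a) && a %in% nn(b)) return("PASS")
  }
  "FAIL"
}

#' Evaluate the three clade criteria for one genome pair
#'
#' Thresholds are inclusive ("at least"): 16S identity >= `s16_min`; ANI
#' >= `ani_min` over an aligned length >= `min_aligned_length`. ANI
#' evidence with aligned length below `min_aligned_length` is MISSING
#' (insufficient alignment), never a FAIL.
#'
#' @param s16_identity Percent 16S identity or `NA` (missing).
#' @param ani_value Percent ANI or `NA` (missing).
#' @param ani_aligned_length Aligned length in bp backing the ANI value.
#' @param tree_relation `"PASS"`/`"FAIL"`/`NA` from [tree_criterion()].
#' @param s16_min,ani_min,min_aligned_length Criterion thresholds.
#' @return Named character vector (`s16`, `ani`, `tree`) over
#'   `"PASS"`/`"FAIL"`/`NA`.
#' @export
evaluate_pair <- function(s16_identity = NA_real_, ani_value = NA_real_,
                          ani_aligned_length = 0L,
                          tree_relation = NA_character_, s16_min = 98.0,
                          ani_min = 95.0, min_aligned_length = 20000L) {
  s16 <- if (is.na(s16_identity)) NA_character_
  else if (s16_identity >= s16_min) "PASS" else "FAIL"
  ani <- if (is.na(ani_value) || ani_aligned_length < min_aligned_length) {
    NA_character_
  } else if (ani_value >= ani_min) "PASS" else "FAIL"
  c(s16 = s16, ani = ani, tree = tree_relation)
}

#' Delineate species-level clades from pairwise evidence
#'
#' Two-phase application of the 2-of-3 evidence rule:
#' * Seeding: pairs with at least two criteria PASS and none FAIL are
#'   grouped and merged transitively; every within-clade pair must keep
#'   zero FAILs (a conflict inside a merged group is an error demanding
#'   manual resolution).
#' * Extension: an unassigned genome joins a clade iff its ANI criterion
#'   is PASS against at least one member and no criterion is FAIL against
#'   any member — missing data is tolerated, conflicting data is not. A
#'   genome qualifying for two clades is an error.
#'
#' Remaining genomes are `NO_CLADE`. Processing order is lexicographic in
#' genome ids, so the partition is invariant to input order.
#'
#' @param evidence `data.frame` with columns `id_a`, `id_b`, `s16`, `ani`,
#'   `tree`, each criterion `"PASS"`/`"FAIL"`/`NA` ([evaluate_pair()] per
#'   pair); pairs may appear in either orientation, missing pairs count as
#'   all-MISSING.
#' @param genome_ids All genome ids to assign.
#' @return A list of class `clade_assignment`: `clades` (named vector
#'   genome id -> clade label or `"NO_CLADE"`), `trail` (per-pair evidence
#'   with the rule outcome).
#' @export
delineate_clades <- function(evidence, genome_ids) {
  genome_ids <- sort(unique(genome_ids))
  need <- c("id_a", "id_b", "s16", "ani", "tree")
  stopifnot(all(need %in% names(evidence)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ev <- stats::setNames(
    lapply(seq_len(nrow(evidence)), function(i) {
      c(s16 = evidence$s16[i], ani = evidence$ani[i], tree = evidence$tree[i])
    }),
    key(evidence$id_a, evidence$id_b)
  )
  get_ev <- function(a, b) {
    ev[[key(a, b)]] %||% c(s16 = NA_character_, ani = NA_character_,
                           tree = NA_character_)
  }
  n_pass <- function(e) sum(e == "PASS", na.rm = TRUE)
  n_fail <- function(e) sum(e == "FAIL", na.rm = TRUE)

  # Phase 1: seed clades from qualifying pairs, merge transitively.
  pairs <- utils::combn(genome_ids, 2L, simplify = FALSE)
  qualifies <- vapply(pairs, function(p) {
    e <- get_ev(p[1], p[2])
    n_pass(e) >= 2L && n_fail(e) == 0L
  }, logical(1))
  comp <- stats::setNames(seq_along(genome_ids), genome_ids)
  find <- function(x) {
    while (comp[[x]] != match(x, genome_ids)) x <- genome_ids[comp[[x]]]
    x
  }
  for (p in pairs[qualifies]) {
    ra <- find(p[1])
    rb <- find(p[2])
    if (ra != rb) comp[[max(ra, rb)]] <- match(min(ra, rb), genome_ids)
  }
  roots <- vapply(genome_ids, find, character(1))
  seeded <- names(table(roots))[table(roots) > 1L]
  clades <- list()
  for (r in sort(seeded)) {
    members <- sort(genome_ids[roots == r])
    for (pp in utils::combn(members, 2L, simplify = FALSE)) {
      e <- get_ev(pp[1], pp[2])
      if (n_fail(e) > 0L) {
        stop("conflicting evidence inside merged clade {",
             paste(members, collapse = ", "), "}: pair ", pp[1], "/", pp[2],
             " has a FAIL; manual resolution required")
      }
    }
    clades[[length(clades) + 1L]] <- members
  }

  # Phase 2: extension by ANI with no conflicting evidence.
  assigned <- unlist(clades)
  for (g in setdiff(genome_ids, assigned)) {
    joinable <- which(vapply(clades, function(members) {
      evs <- lapply(members, function(m) get_ev(g, m))
      any(vapply(evs, function(e) identical(unname(e["ani"]), "PASS"),
                 logical(1))) &&
        !any(vapply(evs, function(e) n_fail(e) > 0L, logical(1)))
    }, logical(1)))
    if (length(joinable) > 1L) {
      stop("genome ", g, " qualifies for ", length(joinable),
           " clades by ANI extension; manual resolution required")
    }
    if (length(joinable) == 1L) {
      clades[[joinable]] <- sort(c(clades[[joinable]], g))
      assigned <- c(assigned, g)
    }
  }

  assignment <- stats::setNames(rep("NO_CLADE", length(genome_ids)),
                                genome_ids)
  ord <- order(vapply(clades, `[`, character(1), 1L))
  for (i in seq_along(ord)) {
    assignment[clades[[ord[i]]]] <- sprintf("clade_%d", i)
  }
  trail <- do.call(rbind, lapply(pairs, function(p) {
    e <- get_ev(p[1], p[2])
    data.frame(id_a = p[1], id_b = p[2], s16 = e[["s16"]], ani = e[["ani"]],
               tree = e[["tree"]], n_pass = n_pass(e), n_fail = n_fail(e),
               same_clade = assignment[[p[1]]] != "NO_CLADE" &&
                 assignment[[p[1]]] == assignment[[p[2]]],
               stringsAsFactors = FALSE)
  }))
  structure(list(clades = assignment, trail = trail),
            class = "clade_assignment")
}

#' Build the pairwise evidence table for clade delineation
#'
#' Computes, for every genome pair, the three criteria consumed by
#' [delineate_clades()]: ANI via [anib()] (with its 20 kb aligned-length
#' floor), 16S identity via [pairwise_16s_identity()] where both genomes
#' have an aligned 16S sequence, and the tree criterion via
#' [tree_criterion()] where both are tree leaves. Genomes below
#' `min_genome_size` are excluded up front (too little sequence for
#' meaningful ANI).
#'
#' @param genomes Named character vector of genome sequences.
#' @param s16_alignment Optional named character vector of aligned 16S
#'   sequences (equal lengths, gaps allowed).
#' @param tree Optional [ape::phylo] tree with genome ids as tip labels.
#' @param s16_min,ani_min,min_aligned_length Criterion thresholds, see
#'   [evaluate_pair()].
#' @param min_genome_size Minimum genome/bin size in bp for inclusion.
#' @return A list: `evidence` (per-pair criterion table for
#'   [delineate_clades()]), `values` (the underlying numeric evidence),
#'   `genome_ids` (ids retained after the size filter).
#' @export
build_clade_evidence <- function(genomes, s16_alignment = NULL, tree = NULL,
                                 s16_min = 98.0, ani_min = 95.0,
                                 min_aligned_length = 20000L,
                                 min_genome_size = 25000L) {
  stopifnot(!is.null(names(genomes)))
  sizes <- nchar(genomes)
  small <- sizes < min_genome_size
  if (any(small)) {
    warning("excluding genome(s) below ", min_genome_size, " bp: ",
            paste(names(genomes)[small], collapse = ", "))
    genomes <- genomes[!small]
  }
  ids <- sort(names(genomes))
  if (length(ids) < 2L) stop("need at least two genomes after size filter")
  pairs <- utils::combn(ids, 2L, simplify = FALSE)
  values <- do.call(rbind, lapply(pairs, function(p) {
    a <- p[1]
    b <- p[2]
    ani <- anib(genomes[[a]], genomes[[b]])
    s16 <- if (!is.null(s16_alignment) &&
                 all(c(a, b) %in% names(s16_alignment))) {
      pairwise_16s_identity(s16_alignment[[a]], s16_alignment[[b]])
    } else NA_real_
    tr <- if (!is.null(tree)) tree_criterion(tree, c(a, b))
    else NA_character_
    data.frame(id_a = a, id_b = b, s16_identity = s16, ani_value = ani$ani,
               ani_aligned_length = ani$aligned_length, tree_relation = tr,
               stringsAsFactors = FALSE)
  }))
  evidence <- do.call(rbind, lapply(seq_len(nrow(values)), function(i) {
    v <- values[i, ]
    e <- evaluate_pair(v$s16_identity, v$ani_value, v$ani_aligned_length,
                       v$tree_relation, s16_min = s16_min,
                       ani_min = ani_min,
                       min_aligned_length = min_aligned_length)
    data.frame(id_a = v$id_a, id_b = v$id_b, s16 = e[["s16"]],
               ani = e[["ani"]], tree = e[["tree"]],
               stringsAsFactors = FALSE)
  }))
  list(evidence = evidence, values = values, genome_ids = ids)
}

#' @export
print.clade_assignment <- function(x, ...) {
  for (cl in unique(x$clades)) {
    cat(sprintf("%s: %s\n", cl,
                paste(names(x$clades)[x$clades == cl], collapse = ", ")))
  }
  invisible(x)
}
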