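#' Read a gene table (GFF3 or TSV)
#'
#' Two dialects are supported and auto-detected:
#' * GFF3 (`##gff-version` pragma or `.gff`/`.gff3` extension): 1-based
#'   inclusive coordinates, converted to 0-based half-open; the functional
#'   category is read from a `category=` attribute (falling back to
#'   `product=`, else `"Unknown"`); only `CDS`/`gene` features are kept.
#' * Tab-separated with header `gene_id  start  end  strand  category`:
#'   coordinates already 0-based half-open, taken as-is.
#'
#' Coding genes whose length is not a multiple of 3 are retained with a
#' warning; downstream degeneracy classification treats them as
#' `other_coding`.
#'
#' @param path Path to the gene table.
#' @return A `data.frame` of gene records (`gene_id`, `start`, `end`,
#'   `strand`, `category`), 0-based half-open.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  first <- readLines(path, n = 1L)
  is_gff <- startsWith(first, "##gff-version") ||
    grepl("\\.gff3?$", path, ignore.case = TRUE)
  genes <- if (is_gff) read_gff3_genes(path) else read_tsv_genes(path)
  if (any(genes$end <= genes$start)) {
    stop("gene with end <= start after coordinate conversion: ",
         paste(genes$gene_id[genes$end <= genes$start], collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("unknown strand for gene(s): ",
         paste(genes$gene_id[!genes$strand %in% c("+", "-")], collapse = ", "))
  }
  notmult <- (genes$end - genes$start) %% 3L != 0L
  if (any(notmult)) {
    warning("gene length not a multiple of 3 for: ",
            paste(genes$gene_id[notmult], collapse = ", "),
            " (retained; excluded from degeneracy classing)")
  }
  genes
}

read_gff3_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) stop("malformed GFF3 line (need 9 columns)")
  type <- vapply(f, `[`, character(1), 3L)
  keep <- type %in% c("CDS", "gene")
  f <- f[keep]
  attr_field <- vapply(f, `[`, character(1), 9L)
  get_attr <- function(key) {
    m <- regmatches(attr_field,
                    regexpr(paste0("(^|;)", key, "=[^;]*"), attr_field))
    out <- rep(NA_character_, length(attr_field))
    hit <- vapply(regmatches(attr_field,
                             gregexpr(paste0("(^|;)", key, "=[^;]*"),
                                      attr_field)),
                  function(x) if (length(x)) sub(paste0(".*", key, "="), "",
                                                 x[[1]]) else NA_character_,
                  character(1))
    hit
  }
  ids <- get_attr("ID")
  ids[is.na(ids)] <- paste0("gene", seq_len(sum(is.na(ids))))
  category <- get_attr("category")
  product <- get_attr("product")
  category[is.na(category)] <- product[is.na(category)]
  category[is.na(category)] <- "Unknown"
  data.frame(
    gene_id = ids,
    start = as.integer(vapply(f, `[`, character(1), 4L)) - 1L,
    end = as.integer(vapply(f, `[`, character(1), 5L)),
    strand = vapply(f, `[`, character(1), 7L),
    category = category,
    stringsAsFactors = FALSE
  )
}

read_tsv_genes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "start", "end", "strand", "category")
  if (!all(need %in% names(df))) {
    stop("TSV gene table must have header columns: ",
         paste(need, collapse = ", "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df[, need, drop = FALSE]
}

#' Write a SNP table as TSV
#'
#' Positions are written 1-based; [read_snp_table()] converts back, so the
#' round trip is the identity.
#'
#' @param snps A SNP table ([call_snps()] output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  out <- snps
  out$pos <- out$pos + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP table written by [write_snp_table()]
#'
#' @param path Path to the TSV.
#' @return A SNP table with 0-based positions.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$pos <- as.integer(df$pos) - 1L
  df
}

#' Read a newick tree
#'
#' Thin wrapper over [ape::read.tree()] that enforces unique leaf labels
#' and flags trees without branch lengths (`topology_only` attribute), in
#' which case patristic distances are unavailable and only topological
#' criteria can be evaluated downstream.
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree: ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  attr(tree, "topology_only") <- is.null(tree$edge.length)
  tree
}
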