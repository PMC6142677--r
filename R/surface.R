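#' Kyte-Doolittle hydropathy scale
#' @return Named numeric vector over the 20 amino acids.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Heuristic cell-surface (external) protein classifier
#'
#' A protein is called `external` iff it has exactly one hydrophobic
#' transmembrane-helix-like motif (a single maximal run of 19-residue
#' windows with mean Kyte-Doolittle hydropathy >= `threshold`) and that
#' motif starts within the first `n_terminal` residues. Sequences shorter
#' than the window are `not_external`.
#'
#' @param protein_sequence Amino-acid string (one-letter codes; a trailing
#'   `*` is tolerated).
#' @param window Window length in residues.
#' @param threshold Mean-hydropathy threshold for a window to count.
#' @param n_terminal The motif must start within this many residues of the
#'   N-terminus.
#' @return `"external"` or `"not_external"`.
#' @export
classify_surface_protein <- function(protein_sequence, window = 19L,
                                     threshold = 1.6, n_terminal = 60L) {
  seq <- toupper(gsub("\\*$", "", protein_sequence))
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  kd <- kyte_doolittle()
  if (!all(aa %in% names(kd))) {
    stop("sequence contains non-standard amino acid(s): ",
         paste(unique(aa[!aa %in% names(kd)]), collapse = ", "))
  }
  n <- length(aa)
  if (n < window) return("not_external")
  h <- kd[aa]
  means <- as.numeric(stats::filter(h, rep(1 / window, window),
                                    sides = 1))[window:n]
  qualifying <- which(means >= threshold) # window start positions, 1-based
  if (length(qualifying) == 0L) return("not_external")
  runs <- split(qualifying, cumsum(c(1L, diff(qualifying) != 1L)))
  if (length(runs) != 1L) return("not_external")
  if (runs[[1]][1] > n_terminal) return("not_external")
  "external"
}
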