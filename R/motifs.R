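# Hydrophobic residues accepted at the C terminus: the mouse TAP transporter
# prefers peptides with hydrophobic C-terminal ends.
HYDROPHOBIC <- c("L", "I", "V", "M", "F")

#' Anchor-residue binding motif for a BALB/c MHC-I allele
#'
#' Default motifs reflect the known pocket preferences of the three alleles:
#' H2-Kd favours tyrosine at position 2 (pocket B) and leucine/isoleucine at
#' the C terminus (pocket F); H2-Dd uses a four-residue motif with glycine at
#' position 2, proline at position 3, lysine at position 5 and a hydrophobic
#' C terminus; the hydrophobic H2-Ld pocket B favours proline at position 2.
#'
#' @param allele One of `"H2-Kd"`, `"H2-Dd"`, `"H2-Ld"`.
#' @return An object of class `anchor_motif`: a list with `allele`,
#'   `positions` (named list, position -> allowed residues) and `c_terminus`
#'   (allowed residues at the last position).
#' @export
anchor_motif <- function(allele) {
  motifs <- list(
    "H2-Kd" = list(positions = list("2" = "Y"), c_terminus = c("L", "I")),
    "H2-Dd" = list(positions = list("2" = "G", "3" = "P", "5" = "K"),
                   c_terminus = HYDROPHOBIC),
    "H2-Ld" = list(positions = list("2" = "P"), c_terminus = HYDROPHOBIC)
  )
  if (!allele %in% names(motifs)) {
    stop("unknown allele: ", allele, " (expected one of ",
         paste(names(motifs), collapse = ", "), ")", call. = FALSE)
  }
  structure(c(list(allele = allele), motifs[[allele]]),
            class = "anchor_motif")
}

# Number of motif rules matched by each peptide (vectorised).
anchor_match_count <- function(peptides, motif) {
  n <- nchar(peptides)
  m <- integer(length(peptides))
  for (pos_chr in names(motif$positions)) {
    pos <- as.integer(pos_chr)
    ok <- n >= pos & substr(peptides, pos, pos) %in% motif$positions[[pos_chr]]
    m <- m + as.integer(ok)
  }
  if (length(motif$c_terminus) > 0) {
    m <- m + as.integer(substr(peptides, n, n) %in% motif$c_terminus)
  }
  m
}
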