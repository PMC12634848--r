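protein_from_id <- function(candidate_id) {
  letter <- substr(candidate_id, 1, 1)
  names(PROTEIN_LETTER)[match(letter, PROTEIN_LETTER)]
}

# Normalise an epitope input: tibble with at least candidate_id or sequence;
# fills protein (from id letter) and length (from sequence) when absent.
as_epitope_table <- function(epitopes) {
  if (is.character(epitopes)) {
    epitopes <- tibble::tibble(sequence = toupper(epitopes))
  }
  epitopes <- tibble::as_tibble(epitopes)
  if (!"protein" %in% names(epitopes) && "candidate_id" %in% names(epitopes)) {
    epitopes$protein <- protein_from_id(epitopes$candidate_id)
  }
  if (!"length" %in% names(epitopes) && "sequence" %in% names(epitopes)) {
    epitopes$length <- nchar(epitopes$sequence)
  }
  epitopes
}

#' Distribution of confirmed epitopes across the viral proteins
#'
#' Counts epitopes per protein (across all alleles) and expresses them as
#' percentages of the total, covering all five proteins including zeros.
#'
#' @param epitopes Epitope tibble (needs `protein`, or `candidate_id` from
#'   which the protein is derived).
#' @return Tibble with columns `protein`, `n`, `pct` over N, P, M, GP, L.
#' @export
protein_distribution <- function(epitopes) {
  epitopes <- as_epitope_table(epitopes)
  n <- vapply(PROTEIN_ORDER,
              function(p) sum(epitopes$protein == p), integer(1))
  total <- sum(n)
  tibble::tibble(
    protein = PROTEIN_ORDER,
    n = unname(n),
    pct = if (total > 0) unname(100 * n / total) else rep(0, length(n))
  )
}

#' Per-allele epitope length distribution
#'
#' @param epitopes Epitope tibble (needs `allele` and `length` or
#'   `sequence`).
#' @return List with `counts` (tibble: `allele`, `length`, `n` over lengths
#'   8-11 for each allele present) and `min_length`/`max_length` over the
#'   observed epitopes (`NA` when empty).
#' @export
length_distribution <- function(epitopes) {
  epitopes <- as_epitope_table(epitopes)
  if (nrow(epitopes) == 0) {
    return(list(counts = tibble::tibble(allele = character(),
                                        length = integer(), n = integer()),
                min_length = NA_integer_, max_length = NA_integer_))
  }
  if (!"allele" %in% names(epitopes)) epitopes$allele <- "all"
  grid <- tidyr::expand_grid(allele = unique(epitopes$allele),
                             length = 8:11)
  obs <- dplyr::count(epitopes, .data$allele, .data$length)
  counts <- dplyr::left_join(grid, obs, by = c("allele", "length"))
  counts$n[is.na(counts$n)] <- 0L
  list(counts = counts,
       min_length = min(epitopes$length),
       max_length = max(epitopes$length))
}

#' Anchor-residue conformity report for one epitope
#'
#' Checks each motif position rule and the C-terminus rule against the
#' epitope sequence. Motif conformity is descriptive only — it is never
#' used to filter confirmed epitopes, since low-affinity epitopes can still
#' be immunogenic.
#'
#' @param sequence Epitope amino-acid sequence.
#' @param motif An [anchor_motif()].
#' @return List with `rules` (tibble: `rule`, `position`, `allowed`,
#'   `residue`, `match`) and `conformant` (all rules matched; vacuously
#'   `TRUE` for an empty motif).
#' @export
anchor_report <- function(sequence, motif) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  pos_rules <- motif$positions
  if (length(pos_rules) > 0 && n < max(as.integer(names(pos_rules)))) {
    stop("epitope shorter than the largest motif anchor position",
         call. = FALSE)
  }
  rows <- list()
  for (pos_chr in names(pos_rules)) {
    pos <- as.integer(pos_chr)
    res <- substr(sequence, pos, pos)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      rule = paste0("position_", pos), position = pos,
      allowed = paste(pos_rules[[pos_chr]], collapse = "/"),
      residue = res, match = res %in% pos_rules[[pos_chr]]
    )
  }
  if (length(motif$c_terminus) > 0) {
    res <- substr(sequence, n, n)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      rule = "c_terminus", position = n,
      allowed = paste(motif$c_terminus, collapse = "/"),
      residue = res, match = res %in% motif$c_terminus
    )
  }
  rules <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(rule = character(), position = integer(),
                   allowed = character(), residue = character(),
                   match = logical())
  list(rules = rules, conformant = all(rules$match))
}

#' Nested epitope pairs within each allele
#'
#' Finds unordered pairs of same-allele epitopes where the shorter sequence
#' is an exact substring of the longer (length-variant epitopes sharing a
#' core, e.g. a 9-mer nested in its 10-mer extension).
#'
#' @param epitopes Epitope tibble (needs `sequence`; `allele` and
#'   `candidate_id` used when present).
#' @return Tibble with one row per unordered pair: `allele`, `shorter_id`,
#'   `longer_id`, `shorter`, `longer`, `length_difference`.
#' @export
nested_pairs <- function(epitopes) {
  epitopes <- as_epitope_table(epitopes)
  if (!"allele" %in% names(epitopes)) epitopes$allele <- "all"
  if (!"candidate_id" %in% names(epitopes)) {
    epitopes$candidate_id <- epitopes$sequence
  }
  epitopes$sequence <- toupper(epitopes$sequence)
  out <- list()
  for (a in unique(epitopes$allele)) {
    e <- epitopes[epitopes$allele == a, ]
    e <- e[order(nchar(e$sequence), e$sequence), ]
    if (nrow(e) < 2) next
    for (i in seq_len(nrow(e) - 1)) {
      for (j in seq(i + 1, nrow(e))) {
        if (nchar(e$sequence[i]) < nchar(e$sequence[j]) &&
            grepl(e$sequence[i], e$sequence[j], fixed = TRUE)) {
          out[[length(out) + 1L]] <- tibble::tibble(
            allele = a,
            shorter_id = e$candidate_id[i], longer_id = e$candidate_id[j],
            shorter = e$sequence[i], longer = e$sequence[j],
            length_difference = nchar(e$sequence[j]) - nchar(e$sequence[i])
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(allele = character(), shorter_id = character(),
                          longer_id = character(), shorter = character(),
                          longer = character(), length_difference = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$allele, .data$shorter)
}

#' Epitope sequences shared between two panels
#'
#' Exact, case-normalised sequence intersection — e.g. epitopes shared
#' between mouse strains with different MHC haplotypes.
#'
#' @param set_a,set_b Character vectors of epitope sequences.
#' @return Character vector of shared sequences (upper case).
#' @export
shared_across_sets <- function(set_a, set_b) {
  intersect(toupper(set_a), toupper(set_b))
}

#' Eligibility of an epitope for pMHC-I multimer production
#'
#' Manufacturers decline multimer production for peptides with predicted
#' binding affinity above 1,000 nM; an affinity exactly at the cutoff
#' counts as eligible.
#'
#' @param affinity_nM Predicted IC50 in nM (vectorised).
#' @param affinity_cutoff_nM Cutoff (default 1000).
#' @return Logical vector; `NA` (indeterminate) where affinity is missing.
#' @export
multimer_eligibility <- function(affinity_nM, affinity_cutoff_nM = 1000) {
  ifelse(is.na(affinity_nM), NA, affinity_nM <= affinity_cutoff_nM)
}

#' The validated VSV-GP BALB/c reference epitope panel
#'
#' The 11 VSV-GP-specific CD8+ T cell epitopes validated for the BALB/c
#' MHC-I alleles, used as the ground-truth identities in end-to-end
#' simulations. Sequences are included where publicly known; four candidate
#' sequences are not available and carry `NA`.
#'
#' @return Tibble with columns `allele`, `candidate_id`, `protein`,
#'   `sequence` (NA where unavailable).
#' @export
validated_epitopes <- function() {
  out <- tibble::tibble(
    allele = c(rep("H2-Kd", 5), rep("H2-Dd", 4), rep("H2-Ld", 2)),
    candidate_id = c("N6", "N7", "N8", "P16", "P25",
                     "P23", "P25", "M33", "M35",
                     "N1", "N13"),
    sequence = c("FHFWGQLTAL", NA, NA, "EYLKSYSRL", "REYLKSYSRL",
                 "FQPKKASLQPL", "RAEKSNYEL", NA, NA,
                 "MPYLIDFGL", "YMPYLIDFGL")
  )
  out$protein <- protein_from_id(out$candidate_id)
  out
}
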