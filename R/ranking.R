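#' Assign binder tiers from predictor percent ranks
#'
#' Binders are tiered on the rank-normalised predictor score: strong below
#' 0.5, weak below 2, marginal below 10, otherwise non-binders. A percent
#' rank exactly at a boundary falls into the weaker tier.
#'
#' @param percent_rank Numeric vector of percent ranks (lower = stronger
#'   predicted binding).
#' @param thresholds Named numeric vector with elements `strong`, `weak`,
#'   `marginal` (upper exclusive bounds).
#' @return Character vector of tiers (`strong`/`weak`/`marginal`/`non`).
#' @export
tier_binders <- function(percent_rank,
                         thresholds = c(strong = 0.5, weak = 2, marginal = 10)) {
  if (any(is.na(percent_rank))) {
    stop("percent_rank missing for one or more peptides", call. = FALSE)
  }
  if (any(percent_rank < 0)) {
    stop("percent_rank must be non-negative", call. = FALSE)
  }
  out <- rep("non", length(percent_rank))
  out[percent_rank < thresholds[["marginal"]]] <- "marginal"
  out[percent_rank < thresholds[["weak"]]] <- "weak"
  out[percent_rank < thresholds[["strong"]]] <- "strong"
  out
}

# Deterministic, platform-stable fractional hash of a string in [0, 1).
# Integer arithmetic kept well below 2^31.
seq_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0L
    for (code in utf8ToInt(s)) h <- (h * 131L + code) %% 100003L
    h / 100003
  }, numeric(1), USE.NAMES = FALSE)
}

#' Deterministic surrogate predictor scores from anchor motifs
#'
#' A lightweight stand-in scorer for running the pipeline without external
#' binding predictors: each peptide is scored by how many allele anchor
#' rules it matches (position-weight style), plus a deterministic
#' sequence-dependent spread so that distinct peptides get distinct scores.
#' More anchor matches always yield a strictly lower percent rank and lower
#' predicted IC50.
#'
#' @param peptide Character vector of 8-11-mer peptides.
#' @param allele One BALB/c MHC-I allele name.
#' @return A tibble with columns `peptide`, `allele`, `affinity_nM`,
#'   `percent_rank`, `stability_score`, `immunogenicity_score`, `tier`.
#' @export
surrogate_score <- function(peptide, allele) {
  motif <- anchor_motif(allele)
  n <- nchar(peptide)
  if (any(n < 8 | n > 11)) {
    stop("peptides must be 8-11 residues long", call. = FALSE)
  }
  m <- anchor_match_count(peptide, motif)
  u <- 0.85 + 0.3 * seq_hash(paste0(allele, ":", peptide))
  percent_rank <- 30 * 6^(-m) * u
  affinity_nM <- 30 + 500 * percent_rank
  tibble::tibble(
    peptide = peptide,
    allele = allele,
    affinity_nM = affinity_nM,
    percent_rank = percent_rank,
    stability_score = 10 - log10(affinity_nM),
    immunogenicity_score = m + (u - 1),
    tier = tier_binders(percent_rank)
  )
}

#' Load predictor score tables
#'
#' Reads tab-separated exports of MHC binding/stability predictors with
#' header columns `peptide`, `allele`, `affinity_nM`, `percent_rank` and
#' optional `stability`, `immunogenicity`. When a peptide universe is given,
#' peptides without any score row are returned flagged unscored.
#'
#' @param table Path to a tab-separated file, or a data frame with the same
#'   columns.
#' @param universe Optional character vector (or tibble with a `peptide`
#'   column) of peptides that should be covered.
#' @return A tibble with columns `peptide`, `allele`, `affinity_nM`,
#'   `percent_rank`, `stability_score`, `immunogenicity_score`, `tier`,
#'   `scored`.
#' @export
load_scores <- function(table, universe = NULL) {
  if (is.character(table)) {
    tab <- readr::read_tsv(table, show_col_types = FALSE,
                           progress = FALSE)
    probs <- readr::problems(tab)
    if (nrow(probs) > 0) {
      stop("malformed score table row at line ", probs$row[1] + 1L, ": ",
           probs$expected[1], call. = FALSE)
    }
  } else {
    tab <- tibble::as_tibble(table)
  }
  required <- c("peptide", "allele", "affinity_nM", "percent_rank")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("score table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"stability" %in% names(tab)) tab$stability <- NA_real_
  if (!"immunogenicity" %in% names(tab)) tab$immunogenicity <- NA_real_
  if (nrow(tab) > 0) {
    if (!is.numeric(tab$affinity_nM) || !is.numeric(tab$percent_rank)) {
      stop("affinity_nM and percent_rank must be numeric", call. = FALSE)
    }
    bad <- which(tab$affinity_nM <= 0)
    if (length(bad) > 0) {
      stop("non-positive predicted affinity at row ", bad[1], call. = FALSE)
    }
    if (any(tab$percent_rank < 0, na.rm = TRUE)) {
      stop("negative percent_rank", call. = FALSE)
    }
  }
  scores <- tibble::tibble(
    peptide = toupper(as.character(tab$peptide)),
    allele = as.character(tab$allele),
    affinity_nM = as.numeric(tab$affinity_nM),
    percent_rank = as.numeric(tab$percent_rank),
    stability_score = as.numeric(tab$stability),
    immunogenicity_score = as.numeric(tab$immunogenicity),
    tier = if (nrow(tab) > 0) tier_binders(tab$percent_rank) else character(),
    scored = TRUE
  )
  if (!is.null(universe)) {
    if (is.data.frame(universe)) universe <- universe$peptide
    universe <- unique(toupper(universe))
    unscored <- setdiff(universe, scores$peptide)
    if (length(unscored) > 0) {
      scores <- dplyr::bind_rows(
        scores,
        tibble::tibble(peptide = unscored, allele = NA_character_,
                       affinity_nM = NA_real_, percent_rank = NA_real_,
                       stability_score = NA_real_,
                       immunogenicity_score = NA_real_,
                       tier = NA_character_, scored = FALSE)
      )
    }
  }
  scores
}

#' Per-protein candidate quotas under the gene-position gradient
#'
#' Sequential transcription of the VSV-GP genome yields a 3' -> 5' protein
#' abundance gradient, mirrored here as a non-increasing per-protein quota:
#' by default 15 candidates from N, 15 from P, 10 from M, 5 from GP and 5
#' from L (budget 50).
#'
#' @param quotas Named non-negative integer vector over the five proteins in
#'   genome order; must be non-increasing.
#' @return The validated quota vector.
#' @export
allocation_scheme <- function(quotas = c(N = 15, P = 15, M = 10, GP = 5, L = 5)) {
  if (!identical(names(quotas), PROTEIN_ORDER)) {
    stop("quotas must be named over proteins in genome order: ",
         paste(PROTEIN_ORDER, collapse = ", "), call. = FALSE)
  }
  if (any(quotas < 0) || any(quotas != round(quotas))) {
    stop("quotas must be non-negative integers", call. = FALSE)
  }
  if (any(diff(quotas) > 0)) {
    stop("quotas must be non-increasing in genome order", call. = FALSE)
  }
  quotas
}

#' Attach predictor scores to enumerated peptide windows
#'
#' Joins a score table onto the peptide universe for one allele, or scores
#' the universe with [surrogate_score()] when no table is given.
#'
#' @param windows Enumerated windows from [enumerate_peptides()].
#' @param allele One BALB/c MHC-I allele name.
#' @param scores Optional score tibble from [load_scores()] (long format
#'   with an `allele` column).
#' @return `windows` with score columns appended; unscored windows carry NA
#'   scores and `scored = FALSE`.
#' @export
score_universe <- function(windows, allele, scores = NULL) {
  if (is.null(scores)) {
    sc <- surrogate_score(unique(windows$peptide), allele)
    sc$scored <- TRUE
  } else {
    sc <- dplyr::filter(scores, .data$allele == !!allele)
    sc <- dplyr::distinct(sc, .data$peptide, .keep_all = TRUE)
  }
  out <- dplyr::left_join(
    windows,
    dplyr::select(sc, "peptide", "affinity_nM", "percent_rank",
                  "stability_score", "immunogenicity_score", "tier",
                  "scored"),
    by = "peptide"
  )
  out$scored[is.na(out$scored)] <- FALSE
  out$allele <- allele
  out
}

# Composite ordering of scored windows: rank-sum over available predictor
# ranks (percent_rank ascending, stability and immunogenicity descending),
# ties broken by affinity, genome position, then sequence.
composite_order <- function(su) {
  ranks <- cbind(
    rank(su$percent_rank, ties.method = "average", na.last = "keep"),
    rank(-su$stability_score, ties.method = "average", na.last = "keep"),
    rank(-su$immunogenicity_score, ties.method = "average", na.last = "keep")
  )
  composite <- rowMeans(ranks, na.rm = TRUE)
  order(composite, su$affinity_nM, match(su$protein, PROTEIN_ORDER),
        su$start, su$peptide)
}

#' Select the per-allele candidate panel under the gradient allocation
#'
#' Takes the quota-best peptides per protein by composite predictor rank,
#' removes duplicate sequences (a peptide occurring in several proteins is
#' attributed to the earlier protein in genome order), cascades unfilled
#' quota slots forward in genome order, and assigns candidate identifiers
#' as protein letter plus global index in genome-then-rank order (with the
#' default scheme: N1-N15, P16-P30, M31-M40, G41-G45, L46-L50).
#'
#' @param scored Scored universe for one allele from [score_universe()].
#' @param allele One BALB/c MHC-I allele name.
#' @param scheme Per-protein quotas from [allocation_scheme()].
#' @return A tibble of candidates: `allele`, `candidate_id`, `sequence`,
#'   `protein`, `start`, `length`, `rank_index`, `tier` and score columns,
#'   ordered by `rank_index`.
#' @export
select_panel <- function(scored, allele, scheme = allocation_scheme()) {
  scheme <- allocation_scheme(scheme)
  budget <- sum(scheme)
  empty <- tibble::tibble(
    allele = character(), candidate_id = character(), sequence = character(),
    protein = character(), start = integer(), length = integer(),
    rank_index = integer(), tier = character(), affinity_nM = numeric(),
    percent_rank = numeric(), stability_score = numeric(),
    immunogenicity_score = numeric()
  )
  if (budget == 0) return(empty)
  su <- dplyr::filter(scored, .data$scored)
  if (nrow(su) == 0) {
    warning("no scored peptides; empty panel", call. = FALSE)
    return(empty)
  }
  # one stimulus per sequence: keep the occurrence in the earliest protein,
  # then the smallest start
  su <- su[order(match(su$protein, PROTEIN_ORDER), su$start, su$length), ]
  su <- su[!duplicated(su$peptide), ]
  su <- su[composite_order(su), ]

  selected <- list()
  carry <- 0L
  for (p in PROTEIN_ORDER) {
    want <- scheme[[p]] + carry
    avail <- su[su$protein == p, ]
    take <- min(want, nrow(avail))
    if (take < want && p != PROTEIN_ORDER[length(PROTEIN_ORDER)]) {
      warning("protein ", p, " has only ", take, " scored peptides for ",
              want, " slots; cascading ", want - take,
              " slot(s) forward in genome order", call. = FALSE)
    }
    carry <- want - take
    if (take > 0) selected[[p]] <- utils::head(avail, take)
  }
  if (carry > 0) {
    warning("panel underfilled: ", carry, " slot(s) could not be filled",
            call. = FALSE)
  }
  panel <- dplyr::bind_rows(selected)
  idx <- seq_len(nrow(panel))
  tibble::tibble(
    allele = allele,
    candidate_id = paste0(PROTEIN_LETTER[panel$protein], idx),
    sequence = panel$peptide,
    protein = panel$protein,
    start = panel$start,
    length = panel$length,
    rank_index = idx,
    tier = panel$tier,
    affinity_nM = panel$affinity_nM,
    percent_rank = panel$percent_rank,
    stability_score = panel$stability_score,
    immunogenicity_score = panel$immunogenicity_score
  )
}
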