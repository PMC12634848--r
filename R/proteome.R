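#' Default FASTA header aliases for the five VSV-GP proteins
#'
#' Headers are tokenised on non-alphanumeric characters and matched
#' case-insensitively against these alias sets.
#'
#' @return Named list mapping protein name to accepted header tokens.
#' @export
default_protein_aliases <- function() {
  list(
    N  = c("N", "NP", "NUCLEOPROTEIN"),
    P  = c("P", "PHOSPHOPROTEIN"),
    M  = c("M", "MATRIX"),
    GP = c("GP", "G", "GLYCOPROTEIN"),
    L  = c("L", "POLYMERASE")
  )
}

validate_protein_sequence <- function(name, sequence) {
  if (!nzchar(sequence)) {
    stop("protein ", name, ": empty sequence", call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0) {
    stop(
      "protein ", name, ": illegal residue '", chars[bad[1]],
      "' at position ", bad[1],
      " (ambiguity codes and non-amino-acid characters are rejected)",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

validate_proteins <- function(proteins) {
  required <- c("name", "order_index", "sequence")
  if (!all(required %in% names(proteins))) {
    stop("proteome table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(proteins))) {
    validate_protein_sequence(proteins$name[i], proteins$sequence[i])
  }
  invisible(proteins)
}

#' Read the ordered VSV-GP proteome from a FASTA file
#'
#' The file must contain exactly five records, one per protein (N, P, M, GP,
#' L), identified by header tokens. Records are returned in genome order
#' (3' -> 5': N, P, M, GP, L) regardless of file order, with `order_index`
#' 1 to 5.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param aliases Named list of accepted header tokens per protein; see
#'   [default_protein_aliases()].
#' @return A tibble with columns `name`, `order_index`, `sequence`.
#' @export
read_proteome <- function(path, aliases = default_protein_aliases()) {
  if (!file.exists(path)) {
    stop("proteome file not found: ", path, call. = FALSE)
  }
  aaset <- Biostrings::readAAStringSet(path)
  headers <- names(aaset)
  assigned <- character(length(aaset))
  for (i in seq_along(headers)) {
    tokens <- strsplit(toupper(headers[i]), "[^A-Z0-9]+")[[1]]
    hit <- names(aliases)[vapply(aliases, function(a) any(tokens %in% a),
                                 logical(1))]
    if (length(hit) == 0) {
      stop("unrecognised FASTA header: '", headers[i], "'", call. = FALSE)
    }
    if (length(hit) > 1) {
      stop("ambiguous FASTA header '", headers[i], "' matches proteins: ",
           paste(hit, collapse = ", "), call. = FALSE)
    }
    assigned[i] <- hit
  }
  dup <- unique(assigned[duplicated(assigned)])
  if (length(dup) > 0) {
    stop("duplicate protein record(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(PROTEIN_ORDER, assigned)
  if (length(missing) > 0) {
    stop("missing protein record(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ord <- match(PROTEIN_ORDER, assigned)
  proteins <- tibble::tibble(
    name = PROTEIN_ORDER,
    order_index = seq_along(PROTEIN_ORDER),
    sequence = unname(toupper(as.character(aaset)))[ord]
  )
  validate_proteins(proteins)
}

#' Write a proteome table back to FASTA
#'
#' @param proteins Proteome tibble as returned by [read_proteome()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteins, path) {
  validate_proteins(proteins)
  aaset <- Biostrings::AAStringSet(proteins$sequence)
  names(aaset) <- proteins$name
  Biostrings::writeXStringSet(aaset, path)
  invisible(path)
}

#' Enumerate all candidate peptide windows of a proteome
#'
#' Produces every window of the requested lengths for every protein, with
#' 1-based inclusive start coordinates within each protein. MHC class I
#' molecules present 8-11-mers, hence the allowed length range.
#'
#' @param proteins Proteome tibble (columns `name`, `order_index`,
#'   `sequence`).
#' @param lengths Integer vector of window lengths, within 8:11.
#' @return A tibble with columns `peptide`, `protein`, `start`, `length`,
#'   ordered by (genome order, start, length).
#' @export
enumerate_peptides <- function(proteins, lengths = 8:11) {
  validate_proteins(proteins)
  lengths <- sort(unique(as.integer(lengths)))
  if (length(lengths) == 0) {
    stop("empty length range", call. = FALSE)
  }
  if (any(lengths < 8L | lengths > 11L)) {
    stop("window lengths must lie within 8..11", call. = FALSE)
  }
  pieces <- list()
  for (i in order(proteins$order_index)) {
    seq_i <- proteins$sequence[i]
    n <- nchar(seq_i)
    for (k in lengths) {
      if (n < k) next
      starts <- seq_len(n - k + 1L)
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        peptide = substring(seq_i, starts, starts + k - 1L),
        protein = proteins$name[i],
        start = starts,
        length = k
      )
    }
  }
  if (length(pieces) == 0) {
    return(tibble::tibble(peptide = character(), protein = character(),
                          start = integer(), length = integer()))
  }
  out <- dplyr::bind_rows(pieces)
  out$ord <- match(out$protein, PROTEIN_ORDER)
  out <- dplyr::arrange(out, .data$ord, .data$start, .data$length)
  out$ord <- NULL
  out
}

#' Locate all exact occurrences of a peptide in the proteome
#'
#' Finds every (possibly overlapping) exact match of the query across all
#' proteins, with 1-based start coordinates.
#'
#' @param sequence Non-empty amino-acid query string.
#' @param proteins Proteome tibble.
#' @return A tibble with columns `protein`, `start`, ordered by
#'   (genome order, start); zero rows when the query is absent.
#' @export
locate_peptide <- function(sequence, proteins) {
  if (!nzchar(sequence)) stop("empty query sequence", call. = FALSE)
  validate_proteins(proteins)
  sequence <- toupper(sequence)
  hits <- list()
  for (i in order(proteins$order_index)) {
    m <- Biostrings::matchPattern(sequence,
                                  Biostrings::AAString(proteins$sequence[i]))
    starts <- Biostrings::start(m)
    if (length(starts) > 0) {
      hits[[length(hits) + 1L]] <- tibble::tibble(
        protein = proteins$name[i], start = sort(starts)
      )
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(protein = character(), start = integer()))
  }
  dplyr::bind_rows(hits)
}
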