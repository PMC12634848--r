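#' Arrange a candidate panel into a two-dimensional pooling matrix
#'
#' Candidates are placed row-major by `rank_index` into an `n_rows` x
#' `n_cols` grid. Each row forms a horizontal pool (pools 1..n_rows) and
#' each column a vertical pool (pools n_rows+1 .. n_rows+n_cols), so every
#' candidate belongs to exactly two pools. With the default 7x7 grid and a
#' 50-candidate panel, the 50th candidate shares the last cell (7, 7) and is
#' flagged `shared_cell`; deconvolution cannot separate co-located
#' candidates, which is resolved at the single-peptide stage.
#'
#' @param panel Candidate tibble from [select_panel()] (needs
#'   `candidate_id` and `rank_index`; `allele` carried through if present).
#' @param n_rows,n_cols Grid dimensions (default 7 x 7, i.e. 14 pools).
#' @param overflow Maximum number of candidates beyond `n_rows * n_cols`
#'   allowed to share the last cell (default 1).
#' @return An object of class `pool_design`: list with `allele`, `n_rows`,
#'   `n_cols` and `layout` (tibble: `candidate_id`, `rank_index`, `row`,
#'   `col`, `row_pool`, `col_pool`, `shared_cell`).
#' @export
build_matrix <- function(panel, n_rows = 7, n_cols = 7, overflow = 1) {
  if (nrow(panel) == 0) stop("empty panel", call. = FALSE)
  if (anyDuplicated(panel$candidate_id)) {
    stop("duplicate candidate_id in panel", call. = FALSE)
  }
  capacity <- n_rows * n_cols
  if (nrow(panel) > capacity + overflow) {
    stop("panel of ", nrow(panel), " exceeds matrix capacity ", capacity,
         " plus overflow allowance ", overflow, call. = FALSE)
  }
  panel <- panel[order(panel$rank_index), ]
  i <- seq_len(nrow(panel))
  row <- ifelse(i <= capacity, ceiling(i / n_cols), n_rows)
  col <- ifelse(i <= capacity, (i - 1L) %% n_cols + 1L, n_cols)
  cell <- paste(row, col)
  layout <- tibble::tibble(
    candidate_id = panel$candidate_id,
    rank_index = panel$rank_index,
    row = as.integer(row),
    col = as.integer(col),
    row_pool = as.integer(row),
    col_pool = as.integer(n_rows + col),
    shared_cell = cell %in% cell[duplicated(cell)]
  )
  allele <- if ("allele" %in% names(panel)) unique(panel$allele) else NA_character_
  structure(
    list(allele = allele, n_rows = n_rows, n_cols = n_cols, layout = layout),
    class = "pool_design"
  )
}

#' @export
print.pool_design <- function(x, ...) {
  cat("pool_design:", x$n_rows, "x", x$n_cols, "matrix",
      if (!is.na(x$allele)) paste0("(", x$allele, ")"), "\n")
  cat("  ", nrow(x$layout), "candidates in", x$n_rows + x$n_cols, "pools;",
      sum(x$layout$shared_cell), "in shared cells\n")
  invisible(x)
}

n_pools <- function(design) design$n_rows + design$n_cols

#' Pool membership of a design
#'
#' @param design A `pool_design`.
#' @return Tibble with columns `pool_id`, `candidate_id`; two rows per
#'   candidate.
#' @export
pool_membership <- function(design) {
  lay <- design$layout
  out <- tibble::tibble(
    pool_id = c(lay$row_pool, lay$col_pool),
    candidate_id = c(lay$candidate_id, lay$candidate_id)
  )
  dplyr::arrange(out, .data$pool_id, .data$candidate_id)
}

#' Pool manifest table for wet-lab pooling
#'
#' @param design A `pool_design`.
#' @return Tibble with one row per (pool, candidate) membership: `allele`,
#'   `pool_id`, `orientation` (`horizontal`/`vertical`), `candidate_id`.
#' @export
pool_manifest <- function(design) {
  memb <- pool_membership(design)
  tibble::tibble(
    allele = design$allele,
    pool_id = memb$pool_id,
    orientation = ifelse(memb$pool_id <= design$n_rows,
                         "horizontal", "vertical"),
    candidate_id = memb$candidate_id
  )
}

#' Deconvolute positive pools into candidate peptides
#'
#' Matrix deconvolution: non-activating pools are crossed out and a
#' candidate is nominated when both of its pools (its row pool and its
#' column pool) are positive. Nominated candidates are ordered by
#' `rank_index`; candidates co-located in a shared cell are additionally
#' reported as ambiguous. Nominated candidates are not yet epitopes —
#' confirmation is a separate single-peptide stage.
#'
#' @param design A `pool_design`.
#' @param positive_pools Integer vector of positive pool ids (subset of
#'   1..n_rows+n_cols; may be empty).
#' @return An object of class `deconvolution_result`: list with `allele`,
#'   `positive_horizontal`, `positive_vertical`, `candidates` (ordered
#'   character vector) and `ambiguous`.
#' @export
decode <- function(design, positive_pools) {
  positive_pools <- as.integer(positive_pools)
  if (anyNA(positive_pools) ||
      any(positive_pools < 1L | positive_pools > n_pools(design))) {
    stop("unknown pool id; pool ids are 1..", n_pools(design), call. = FALSE)
  }
  positive_pools <- unique(positive_pools)
  lay <- design$layout
  hit <- lay$row_pool %in% positive_pools & lay$col_pool %in% positive_pools
  nominated <- lay[hit, ]
  nominated <- nominated[order(nominated$rank_index), ]
  structure(
    list(
      allele = design$allele,
      positive_horizontal = sort(positive_pools[positive_pools <= design$n_rows]),
      positive_vertical = sort(positive_pools[positive_pools > design$n_rows]),
      candidates = nominated$candidate_id,
      ambiguous = nominated$candidate_id[nominated$shared_cell]
    ),
    class = "deconvolution_result"
  )
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("deconvolution", if (!is.na(x$allele)) paste0("(", x$allele, ")"), ":",
      length(x$positive_horizontal), "horizontal +",
      length(x$positive_vertical), "vertical positive pools ->",
      length(x$candidates), "candidate(s)\n")
  if (length(x$candidates)) {
    cat("  candidates:", paste(x$candidates, collapse = ", "), "\n")
  }
  if (length(x$ambiguous)) {
    cat("  ambiguous (shared cell):", paste(x$ambiguous, collapse = ", "), "\n")
  }
  invisible(x)
}
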