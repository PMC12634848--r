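#' Configuration of the ELISpot positivity calling
#'
#' Positivity combines an unpaired two-sample t test (treated vs untreated
#' spot counts) with a biological-relevance floor: the treated group mean
#' must reach the minimum spot count (60 by default) in addition to
#' statistical significance. The same 60-count threshold is also applied to
#' the positive control in plate QC.
#'
#' @param alpha Significance level (default 0.05).
#' @param floor Minimum treated-group mean spot count (default 60).
#' @param test `"student"` (equal-variance, the common graphing-software
#'   default) or `"welch"`.
#' @param multiplicity `"none"` (per-stimulus raw tests, default) or `"BH"`
#'   (Benjamini-Hochberg across the stimuli of one call set).
#' @param background_ceiling Maximum acceptable negative-control mean in QC
#'   (default 50).
#' @param saturation Optional cap applied to saturated counts; `NULL`
#'   (default) drops non-finite counts with a warning.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(alpha = 0.05, floor = 60,
                          test = c("student", "welch"),
                          multiplicity = c("none", "BH"),
                          background_ceiling = 50,
                          saturation = NULL) {
  test <- match.arg(test)
  multiplicity <- match.arg(multiplicity)
  stopifnot(alpha > 0, alpha < 1, floor >= 0, background_ceiling >= 0)
  structure(list(alpha = alpha, floor = floor, test = test,
                 multiplicity = multiplicity,
                 background_ceiling = background_ceiling,
                 saturation = saturation),
            class = "screen_config")
}

validate_wells <- function(wells) {
  required <- c("mouse_id", "group", "stimulus", "spots")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols) > 0) {
    stop("well table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(wells) == 0) stop("no wells", call. = FALSE)
  bad_group <- setdiff(unique(wells$group), c("control", "treated"))
  if (length(bad_group) > 0) {
    stop("unknown group value(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  if (any(wells$spots < 0, na.rm = TRUE)) {
    stop("negative spot counts", call. = FALSE)
  }
  invisible(wells)
}

# Apply the saturation policy to a numeric count vector.
handle_saturation <- function(spots, config) {
  sat <- !is.finite(spots)
  if (!any(sat)) return(spots)
  if (is.null(config$saturation)) {
    warning(sum(sat), " saturated well(s) excluded", call. = FALSE)
    spots[!sat]
  } else {
    spots[sat] <- config$saturation
    spots
  }
}

#' Plate quality control on assay controls
#'
#' Checks, per group, that negative-control (NC) and positive-control (PC)
#' wells are present, that the PC mean reaches the spot-count floor and
#' that the NC mean stays below the background ceiling.
#'
#' @param wells Well table (columns `mouse_id`, `group`, `stimulus`,
#'   `spots`) containing `NC` and `PC` stimuli.
#' @param config A [screen_config()].
#' @return List with `pass` (logical) and `checks` (tibble: `group`,
#'   `check`, `value`, `pass`, `reason`).
#' @export
qc_plate <- function(wells, config = screen_config()) {
  validate_wells(wells)
  checks <- list()
  for (g in sort(unique(wells$group))) {
    for (ctl in c("NC", "PC")) {
      w <- wells[wells$group == g & wells$stimulus == ctl, ]
      if (nrow(w) == 0) {
        checks[[length(checks) + 1L]] <- tibble::tibble(
          group = g, check = ctl, value = NA_real_, pass = FALSE,
          reason = paste0("missing ", if (ctl == "NC") "negative" else
                          "positive", " control")
        )
        next
      }
      m <- mean(handle_saturation(w$spots, config))
      ok <- if (ctl == "PC") m >= config$floor else m <= config$background_ceiling
      checks[[length(checks) + 1L]] <- tibble::tibble(
        group = g, check = ctl, value = m, pass = ok,
        reason = dplyr::case_when(
          ok ~ "",
          ctl == "PC" ~ "positive control below floor",
          TRUE ~ "negative control above background ceiling"
        )
      )
    }
  }
  checks <- dplyr::bind_rows(checks)
  list(pass = all(checks$pass), checks = checks)
}

# Core positivity call on two count vectors. A group with fewer than two
# wells yields an indeterminate (never positive) call.
call_counts <- function(treated, control, stimulus, config) {
  treated <- handle_saturation(treated, config)
  control <- handle_saturation(control, config)
  mt <- if (length(treated)) mean(treated) else NA_real_
  mc <- if (length(control)) mean(control) else NA_real_
  indeterminate <- length(treated) < 2 || length(control) < 2
  p <- NA_real_
  if (!indeterminate) {
    p <- tryCatch(
      t.test(treated, control,
             var.equal = (config$test == "student"))$p.value,
      error = function(e) NA_real_  # constant data: no evidence either way
    )
  }
  passes_floor <- !is.na(mt) && mt >= config$floor
  positive <- !indeterminate && !is.na(p) && p < config$alpha &&
    passes_floor && mt > mc
  tibble::tibble(
    stimulus = stimulus,
    n_treated = length(treated), n_control = length(control),
    mean_treated = mt, mean_control = mc,
    p_value = p, passes_floor = passes_floor,
    indeterminate = indeterminate, positive = positive
  )
}

#' Positivity call for one stimulus
#'
#' Unpaired two-sample t test of treated versus control spot counts;
#' positive iff p < alpha AND the treated mean reaches the floor AND the
#' treated mean exceeds the control mean.
#'
#' @param wells Well table restricted to a single stimulus.
#' @param config A [screen_config()].
#' @return One-row tibble with the call (see [call_counts] fields).
#' @export
call_stimulus <- function(wells, config = screen_config()) {
  validate_wells(wells)
  stim <- unique(wells$stimulus)
  if (length(stim) != 1) {
    stop("call_stimulus expects wells for exactly one stimulus", call. = FALSE)
  }
  call_counts(wells$spots[wells$group == "treated"],
              wells$spots[wells$group == "control"], stim, config)
}

parse_stimulus_id <- function(stimulus, prefix) {
  sub(paste0("^", prefix, ":"), "", stimulus)
}

#' Call positivity of all pools on a plate
#'
#' One call per pool of the design (stimulus labels `pool:<id>`); pools
#' without wells are marked indeterminate. The positive set is partitioned
#' into horizontal and vertical pools by the design orientation. With
#' `multiplicity = "BH"` in the config, p values are Benjamini-Hochberg
#' adjusted across pools before calling.
#'
#' @param wells Well table covering the pool stimuli.
#' @param design A `pool_design`.
#' @param config A [screen_config()].
#' @return List with `calls` (tibble, one row per pool, including
#'   `pool_id`), `positive_pools`, `positive_horizontal`,
#'   `positive_vertical`.
#' @export
call_pools <- function(wells, design, config = screen_config()) {
  validate_wells(wells)
  calls <- list()
  for (pid in seq_len(n_pools(design))) {
    w <- wells[wells$stimulus == paste0("pool:", pid), ]
    if (nrow(w) == 0) {
      calls[[pid]] <- tibble::tibble(
        stimulus = paste0("pool:", pid), n_treated = 0L, n_control = 0L,
        mean_treated = NA_real_, mean_control = NA_real_, p_value = NA_real_,
        passes_floor = FALSE, indeterminate = TRUE, positive = FALSE
      )
    } else {
      calls[[pid]] <- call_counts(w$spots[w$group == "treated"],
                                  w$spots[w$group == "control"],
                                  paste0("pool:", pid), config)
    }
  }
  calls <- dplyr::bind_rows(calls)
  calls <- dplyr::mutate(calls, pool_id = seq_len(n_pools(design)),
                         .before = 1)
  if (config$multiplicity == "BH") {
    calls$p_adjusted <- p.adjust(calls$p_value, method = "BH")
    calls$positive <- !calls$indeterminate & !is.na(calls$p_adjusted) &
      calls$p_adjusted < config$alpha & calls$passes_floor &
      calls$mean_treated > calls$mean_control
  }
  pos <- calls$pool_id[calls$positive]
  list(
    calls = calls,
    positive_pools = pos,
    positive_horizontal = pos[pos <= design$n_rows],
    positive_vertical = pos[pos > design$n_rows]
  )
}

#' Confirm decoded candidates at the single-peptide stage
#'
#' Each nominated candidate is tested individually (stimulus labels
#' `peptide:<candidate_id>`) with the same positivity rule as the pool
#' stage; candidates passing become ELISpot-confirmed epitopes.
#'
#' @param wells Well table of the single-peptide plate.
#' @param candidates Character vector of candidate ids, or a candidate
#'   tibble with a `candidate_id` column (extra columns are carried
#'   through).
#' @param config A [screen_config()].
#' @return Tibble with one row per candidate: candidate columns, the call
#'   fields, and `elispot_confirmed`.
#' @export
confirm_peptides <- function(wells, candidates, config = screen_config()) {
  if (is.character(candidates)) {
    candidates <- tibble::tibble(candidate_id = candidates)
  }
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, elispot_confirmed = logical(0)))
  }
  validate_wells(wells)
  calls <- list()
  for (i in seq_len(nrow(candidates))) {
    id <- candidates$candidate_id[i]
    w <- wells[wells$stimulus == paste0("peptide:", id), ]
    if (nrow(w) == 0) {
      warning("candidate ", id, " has no single-peptide wells; ",
              "left unconfirmed", call. = FALSE)
      calls[[i]] <- tibble::tibble(
        stimulus = paste0("peptide:", id), n_treated = 0L, n_control = 0L,
        mean_treated = NA_real_, mean_control = NA_real_, p_value = NA_real_,
        passes_floor = FALSE, indeterminate = TRUE, positive = FALSE
      )
    } else {
      calls[[i]] <- call_counts(w$spots[w$group == "treated"],
                                w$spots[w$group == "control"],
                                paste0("peptide:", id), config)
    }
  }
  calls <- dplyr::bind_rows(calls)
  out <- dplyr::bind_cols(candidates,
                          dplyr::select(calls, -"stimulus"))
  out$elispot_confirmed <- calls$positive
  out
}

#' Run the full two-stage matrix screen
#'
#' Per allele: pool positivity calling, matrix deconvolution of the
#' positive pools, then single-peptide confirmation of the nominated
#' candidates. Candidates are only ever confirmed from within the decoded
#' set; if the single-peptide stage has no wells for an allele, its decoded
#' list is kept and its confirmed list is empty.
#'
#' @param pool_wells Well table of the pool stage (with an `allele` column
#'   when several alleles are screened together).
#' @param peptide_wells Well table of the single-peptide stage (may be
#'   `NULL`).
#' @param designs A `pool_design` or named list of designs keyed by allele.
#' @param panels Optional candidate tibble (or named list) used to attach
#'   candidate annotation to confirmed epitopes.
#' @param config A [screen_config()].
#' @return An object of class `screen_result`: list with `per_allele`
#'   (each: `pool_calls`, `decoded`, `peptide_calls`), `decoded` (tibble)
#'   and `confirmed` (tibble of ELISpot-confirmed epitopes).
#' @export
two_stage_screen <- function(pool_wells, peptide_wells, designs,
                             panels = NULL, config = screen_config()) {
  if (inherits(designs, "pool_design")) {
    designs <- stats::setNames(list(designs), designs$allele)
  }
  if (is.data.frame(panels)) {
    panels <- split(panels, panels$allele)
  }
  per_allele <- list()
  decoded_all <- list()
  confirmed_all <- list()
  for (a in names(designs)) {
    design <- designs[[a]]
    pw <- if ("allele" %in% names(pool_wells)) {
      pool_wells[pool_wells$allele == a, ]
    } else pool_wells
    stage1 <- call_pools(pw, design, config)
    dec <- decode(design, stage1$positive_pools)
    cand <- tibble::tibble(allele = a, candidate_id = dec$candidates)
    if (!is.null(panels) && a %in% names(panels)) {
      cand <- dplyr::left_join(cand, panels[[a]],
                               by = c("allele", "candidate_id"))
    }
    sw <- peptide_wells
    if (!is.null(sw) && "allele" %in% names(sw)) sw <- sw[sw$allele == a, ]
    if (is.null(sw) || nrow(sw) == 0 || nrow(cand) == 0) {
      pep_calls <- dplyr::mutate(cand, elispot_confirmed = FALSE)
      if (nrow(cand) == 0) pep_calls$elispot_confirmed <- logical(0)
    } else {
      pep_calls <- confirm_peptides(sw, cand, config)
    }
    per_allele[[a]] <- list(pool_calls = stage1, decoded = dec,
                            peptide_calls = pep_calls)
    decoded_all[[a]] <- cand
    confirmed_all[[a]] <- pep_calls[pep_calls$elispot_confirmed, , drop = FALSE]
  }
  structure(
    list(per_allele = per_allele,
         decoded = dplyr::bind_rows(decoded_all),
         confirmed = dplyr::bind_rows(confirmed_all)),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat("two-stage screen across", length(x$per_allele), "allele(s)\n")
  for (a in names(x$per_allele)) {
    pa <- x$per_allele[[a]]
    cat(sprintf(
      "  %s: %d positive pools -> %d decoded -> %d confirmed\n", a,
      length(pa$pool_calls$positive_pools), length(pa$decoded$candidates),
      sum(pa$peptide_calls$elispot_confirmed)))
  }
  cat("confirmed epitopes:", nrow(x$confirmed), "\n")
  invisible(x)
}
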