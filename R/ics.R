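#' IFN-gamma-positive frequency among CD8+ events
#'
#' @param positive_events Count of IFN-gamma-positive CD8+ events.
#' @param total_cd8_events Total gated CD8+ events.
#' @param digits Decimal places for the reported percentage (default 2,
#'   the reporting convention); `NULL` for full precision.
#' @return Percentage in \[0, 100\]; `NA` (with a warning) when the total
#'   is zero.
#' @export
ifng_frequency <- function(positive_events, total_cd8_events, digits = 2) {
  if (any(positive_events < 0 | total_cd8_events < 0)) {
    stop("event counts must be non-negative", call. = FALSE)
  }
  if (any(positive_events > total_cd8_events)) {
    stop("positive events exceed total CD8+ events", call. = FALSE)
  }
  out <- 100 * positive_events / total_cd8_events
  if (any(total_cd8_events == 0)) {
    warning("zero total CD8+ events: frequency undefined", call. = FALSE)
    out[total_cd8_events == 0] <- NA_real_
  }
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Pearson correlation between ELISpot and ICS readouts
#'
#' Cross-assay validation: per-stimulus mean IFN-gamma spot counts against
#' per-stimulus mean IFN-gamma-positive CD8+ frequencies.
#'
#' @param elispot_means,ics_means Paired numeric vectors (one entry per
#'   stimulus), length >= 3.
#' @return One-row tibble with `r`, `p_value`, `n`, `flagged` (`TRUE` when
#'   a vector has zero variance and r is undefined).
#' @export
correlate_assays <- function(elispot_means, ics_means) {
  if (length(elispot_means) != length(ics_means)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(elispot_means) & !is.na(ics_means)
  x <- elispot_means[ok]
  y <- ics_means[ok]
  if (length(x) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(tibble::tibble(r = NA_real_, p_value = NA_real_,
                          n = length(x), flagged = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), flagged = FALSE)
}

#' Compare treatment routes per stimulus (two-way ANOVA + Tukey)
#'
#' Fits a two-factor model `freq_ifng ~ stimulus * route` and reports
#' Tukey-adjusted pairwise route contrasts within each stimulus.
#'
#' @param ics ICS table with columns `route`, `stimulus`, `freq_ifng`.
#' @param stimuli Optional stimulus subset (default: all peptide stimuli
#'   present).
#' @param routes Optional route subset (default: all routes present).
#' @param alpha Significance level for flagging contrasts (default 0.05).
#' @return Tibble with one row per (stimulus, route contrast): `stimulus`,
#'   `contrast`, `estimate`, `se`, `df`, `p_value` (Tukey-adjusted),
#'   `significant`.
#' @export
compare_routes <- function(ics, stimuli = NULL, routes = NULL, alpha = 0.05) {
  required <- c("route", "stimulus", "freq_ifng")
  if (!all(required %in% names(ics))) {
    stop("ICS table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(stimuli)) {
    stimuli <- unique(grep("^peptide:", ics$stimulus, value = TRUE))
    if (length(stimuli) == 0) stimuli <- setdiff(unique(ics$stimulus),
                                                 c("NC", "PC"))
  }
  if (is.null(routes)) routes <- unique(ics$route)
  d <- ics[ics$stimulus %in% stimuli & ics$route %in% routes, ]
  counts <- dplyr::count(d, .data$stimulus, .data$route)
  thin <- counts[counts$n < 2, ]
  if (nrow(thin) > 0) {
    warning("dropping stimulus x route cells with < 2 mice: ",
            paste(paste(thin$stimulus, thin$route, sep = "/"),
                  collapse = ", "), call. = FALSE)
    d <- dplyr::anti_join(d, thin[, c("stimulus", "route")],
                          by = c("stimulus", "route"))
  }
  if (length(unique(d$route)) < 2) {
    stop("need at least two routes to compare", call. = FALSE)
  }
  d$stimulus <- factor(d$stimulus)
  d$route <- factor(d$route)
  fit <- aov(freq_ifng ~ stimulus * route, data = d)
  emm <- emmeans::emmeans(fit, ~ route | stimulus)
  contr <- summary(emmeans::contrast(emm, method = "pairwise",
                                     adjust = "tukey"))
  out <- tibble::tibble(
    stimulus = as.character(contr$stimulus),
    contrast = as.character(contr$contrast),
    estimate = contr$estimate,
    se = contr$SE,
    df = contr$df,
    p_value = contr$p.value,
    significant = !is.na(contr$p.value) & contr$p.value < alpha
  )
  skipped <- is.na(out$estimate)
  if (any(skipped)) {
    warning("contrast(s) skipped for missing route level: ",
            paste(paste(out$stimulus[skipped], out$contrast[skipped],
                        sep = " "), collapse = "; "), call. = FALSE)
  }
  out
}

#' Epitope composition of the virus-specific CD8+ response
#'
#' Mean IFN-gamma-positive frequency per epitope stimulus, background
#' (negative control) subtracted, negatives clamped to zero, then
#' normalised to relative proportions (the pie-chart view of which epitopes
#' carry the response).
#'
#' @param ics ICS table with columns `stimulus`, `freq_ifng`.
#' @param epitopes Character vector of epitope stimulus labels (either the
#'   raw stimulus strings or candidate ids matched as `peptide:<id>`).
#' @param nc_label Negative-control stimulus label (default `"NC"`).
#' @param subtract_background Subtract the NC mean before normalising
#'   (default TRUE).
#' @return List with `summary` (tibble: `stimulus`, `mean_freq`,
#'   `adjusted_mean`, `proportion`) and `flagged` (`TRUE` when no epitope
#'   retains signal after subtraction, in which case proportions are `NA`).
#' @export
epitope_composition <- function(ics, epitopes, nc_label = "NC",
                                subtract_background = TRUE) {
  labels <- ifelse(epitopes %in% ics$stimulus, epitopes,
                   paste0("peptide:", epitopes))
  missing <- labels[!labels %in% ics$stimulus]
  if (length(missing) > 0) {
    stop("no ICS rows for stimulus/stimuli: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  means <- vapply(labels, function(s) mean(ics$freq_ifng[ics$stimulus == s]),
                  numeric(1))
  nc_mean <- if (subtract_background && any(ics$stimulus == nc_label)) {
    mean(ics$freq_ifng[ics$stimulus == nc_label])
  } else 0
  adjusted <- pmax(means - nc_mean, 0)
  flagged <- sum(adjusted) == 0
  proportion <- if (flagged) rep(NA_real_, length(adjusted)) else
    adjusted / sum(adjusted)
  if (flagged) {
    warning("no signal above background: proportions undefined",
            call. = FALSE)
  }
  list(
    summary = tibble::tibble(stimulus = unname(labels),
                             mean_freq = unname(means),
                             adjusted_mean = unname(adjusted),
                             proportion = unname(proportion)),
    flagged = flagged
  )
}

#' Polyfunctionality gate frequencies
#'
#' Converts event counts over the eight Boolean combinations of IFN-gamma,
#' TNF-alpha and CD107a into per-combination percentages of CD8+ events and
#' summarises the single-, double- and triple-positive classes.
#'
#' @param counts Data frame with logical (or 0/1) columns `ifng`, `tnfa`,
#'   `cd107a` and a `count` column; all eight combinations must be present
#'   exactly once.
#' @param total Optional total CD8+ event count; must equal `sum(counts$count)`
#'   when supplied.
#' @return List with `combinations` (tibble: the eight combinations with
#'   `count`, `freq`, `n_positive`) and `classes` (tibble: `class` in
#'   none/single/double/triple with summed `freq`).
#' @export
polyfunction_gates <- function(counts, total = NULL) {
  required <- c("ifng", "tnfa", "cd107a", "count")
  if (!all(required %in% names(counts))) {
    stop("counts needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  counts <- tibble::as_tibble(counts)
  for (m in c("ifng", "tnfa", "cd107a")) counts[[m]] <- as.logical(counts[[m]])
  key <- paste(counts$ifng, counts$tnfa, counts$cd107a)
  full <- expand.grid(ifng = c(FALSE, TRUE), tnfa = c(FALSE, TRUE),
                      cd107a = c(FALSE, TRUE))
  full_key <- paste(full$ifng, full$tnfa, full$cd107a)
  if (nrow(counts) != 8 || anyDuplicated(key) || !setequal(key, full_key)) {
    stop("counts must cover all 8 marker combinations exactly once",
         call. = FALSE)
  }
  if (any(counts$count < 0)) stop("negative event counts", call. = FALSE)
  tot <- sum(counts$count)
  if (!is.null(total) && total != tot) {
    stop("combination counts (", tot, ") do not sum to total (", total, ")",
         call. = FALSE)
  }
  counts$freq <- if (tot > 0) 100 * counts$count / tot else
    rep(NA_real_, 8)
  counts$n_positive <- counts$ifng + counts$tnfa + counts$cd107a
  classes <- tibble::tibble(
    class = c("none", "single", "double", "triple"),
    freq = vapply(0:3, function(k) sum(counts$freq[counts$n_positive == k]),
                  numeric(1))
  )
  list(combinations = counts, classes = classes)
}
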