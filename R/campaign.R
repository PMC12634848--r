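#' Configuration of an end-to-end screening campaign
#'
#' @param proteome Path to a proteome FASTA, or a proteome tibble.
#' @param alleles MHC-I alleles to screen (default all three BALB/c
#'   alleles).
#' @param scheme Per-protein quotas from [allocation_scheme()].
#' @param n_rows,n_cols Pooling-matrix dimensions.
#' @param screen A [screen_config()].
#' @param sim A [simulation_config()] used to generate assay data, or
#'   `NULL` when real well tables are supplied.
#' @param scores Optional predictor score table (path or tibble for
#'   [load_scores()]); the surrogate scorer is used when absent.
#' @param pool_wells,peptide_wells Optional measured well tables (path or
#'   tibble) used instead of simulation.
#' @param out_dir Optional output directory for campaign artifacts.
#' @return A list of class `campaign_config`.
#' @export
campaign_config <- function(proteome, alleles = balbc_alleles(),
                            scheme = allocation_scheme(),
                            n_rows = 7, n_cols = 7,
                            screen = screen_config(),
                            sim = simulation_config(),
                            scores = NULL, pool_wells = NULL,
                            peptide_wells = NULL, out_dir = NULL) {
  if (is.character(proteome) && !file.exists(proteome)) {
    stop("campaign config: proteome file not found: ", proteome,
         call. = FALSE)
  }
  if (length(alleles) == 0) {
    stop("campaign config: alleles must be non-empty", call. = FALSE)
  }
  if (is.null(sim) && is.null(pool_wells)) {
    stop("campaign config: either a simulation config or pool well data ",
         "is required", call. = FALSE)
  }
  structure(list(proteome = proteome, alleles = alleles, scheme = scheme,
                 n_rows = n_rows, n_cols = n_cols, screen = screen,
                 sim = sim, scores = scores, pool_wells = pool_wells,
                 peptide_wells = peptide_wells, out_dir = out_dir),
            class = "campaign_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

read_wells_input <- function(x) {
  if (is.character(x)) {
    readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(x)
  }
}

#' Run a screening campaign end to end
#'
#' Executes enumerate -> score -> select -> design -> (simulate or ingest
#' wells) -> pool calling -> deconvolution -> single-peptide confirmation
#' -> characterization. With an output directory set, writes the panel
#' manifest, pool manifest, per-stage calls, confirmed epitope table, a
#' machine-readable JSON summary and a log of thresholds and seeds; reruns
#' with the same configuration and seed produce byte-identical
#' machine-readable outputs.
#'
#' @param config A [campaign_config()].
#' @return A list of class `epitope_campaign` with elements `panels`,
#'   `designs`, `pool_calls`, `decoded`, `confirmed`, `characterization`,
#'   `pool_wells`, `peptide_wells` and `config`.
#' @export
run_campaign <- function(config) {
  if (!inherits(config, "campaign_config")) {
    stop("config must be a campaign_config", call. = FALSE)
  }
  proteins <- stage("proteome", {
    if (is.character(config$proteome)) read_proteome(config$proteome)
    else validate_proteins(tibble::as_tibble(config$proteome))
  })
  windows <- stage("enumerate", enumerate_peptides(proteins))
  scores <- stage("scores", {
    if (is.null(config$scores)) NULL else load_scores(config$scores)
  })

  panels <- list()
  designs <- list()
  for (a in config$alleles) {
    panels[[a]] <- stage("select_panel", {
      select_panel(score_universe(windows, a, scores), a, config$scheme)
    })
    designs[[a]] <- stage("build_matrix", {
      build_matrix(panels[[a]], config$n_rows, config$n_cols)
    })
  }

  simulate <- is.null(config$pool_wells)
  pool_wells <- stage("pool_wells", {
    if (simulate) {
      dplyr::bind_rows(lapply(config$alleles, function(a) {
        simulate_pool_plate(config$sim, designs[[a]],
                            seed = derive_seed(config$sim$seed,
                                               paste0("pool:", a)))
      }))
    } else read_wells_input(config$pool_wells)
  })

  pool_calls <- list()
  decoded <- list()
  peptide_wells <- list()
  confirmed <- list()
  peptide_calls <- list()
  for (a in config$alleles) {
    pw <- pool_wells[pool_wells$allele == a, ]
    stage1 <- stage("call_pools", call_pools(pw, designs[[a]], config$screen))
    dec <- stage("decode", decode(designs[[a]], stage1$positive_pools))
    cand <- panels[[a]][panels[[a]]$candidate_id %in% dec$candidates, ]
    sw <- stage("peptide_wells", {
      if (simulate) {
        simulate_peptide_plate(config$sim, dec$candidates, allele = a,
                               seed = derive_seed(config$sim$seed,
                                                  paste0("peptide:", a)))
      } else if (!is.null(config$peptide_wells)) {
        w <- read_wells_input(config$peptide_wells)
        if ("allele" %in% names(w)) w[w$allele == a, ] else w
      } else NULL
    })
    pep <- stage("confirm_peptides", {
      if (is.null(sw) || nrow(sw) == 0 || nrow(cand) == 0) {
        dplyr::mutate(cand, elispot_confirmed = FALSE)
      } else {
        confirm_peptides(sw, cand, config$screen)
      }
    })
    pool_calls[[a]] <- dplyr::mutate(stage1$calls, allele = a, .before = 1)
    decoded[[a]] <- cand
    peptide_wells[[a]] <- sw
    peptide_calls[[a]] <- pep
    confirmed[[a]] <- pep[pep$elispot_confirmed, , drop = FALSE]
  }
  pool_calls <- dplyr::bind_rows(pool_calls)
  decoded <- dplyr::bind_rows(decoded)
  confirmed <- dplyr::bind_rows(confirmed)

  characterization <- stage("characterize", list(
    protein_distribution = protein_distribution(confirmed),
    length_distribution = length_distribution(confirmed),
    nested_pairs = if (nrow(confirmed) > 0)
      nested_pairs(confirmed) else NULL,
    multimer_eligible = if (nrow(confirmed) > 0)
      confirmed$candidate_id[
        !is.na(multimer_eligibility(confirmed$affinity_nM)) &
          multimer_eligibility(confirmed$affinity_nM)] else character()
  ))

  result <- structure(
    list(panels = panels, designs = designs, pool_calls = pool_calls,
         decoded = decoded, confirmed = confirmed,
         peptide_calls = dplyr::bind_rows(peptide_calls),
         characterization = characterization,
         pool_wells = pool_wells,
         peptide_wells = dplyr::bind_rows(peptide_wells),
         config = config),
    class = "epitope_campaign"
  )
  if (!is.null(config$out_dir)) write_campaign(result, config$out_dir)
  result
}

#' @export
print.epitope_campaign <- function(x, ...) {
  cat("epitope campaign over", length(x$panels), "allele(s)\n")
  for (a in names(x$panels)) {
    pos <- x$pool_calls[x$pool_calls$allele == a & x$pool_calls$positive, ]
    cat(sprintf("  %s: panel %d, %d positive pools, %d decoded, %d confirmed\n",
                a, nrow(x$panels[[a]]), nrow(pos),
                sum(x$decoded$allele == a),
                sum(x$confirmed$allele == a)))
  }
  cat("total confirmed epitopes:", nrow(x$confirmed), "\n")
  invisible(x)
}

#' Write campaign artifacts to a directory
#'
#' @param campaign An `epitope_campaign`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_campaign <- function(campaign, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
  }
  tsv(dplyr::bind_rows(campaign$panels), "panel_manifest.tsv")
  tsv(dplyr::bind_rows(lapply(campaign$designs, pool_manifest)),
      "pool_manifest.tsv")
  tsv(campaign$pool_calls, "pool_calls.tsv")
  tsv(campaign$decoded, "decoded_candidates.tsv")
  tsv(campaign$confirmed, "confirmed_epitopes.tsv")
  cfg <- campaign$config
  summary <- list(
    seed = if (!is.null(cfg$sim)) cfg$sim$seed else NULL,
    alleles = cfg$alleles,
    alpha = cfg$screen$alpha,
    floor = cfg$screen$floor,
    test = cfg$screen$test,
    panel_size = vapply(campaign$panels, nrow, integer(1)),
    positive_pools = lapply(stats::setNames(cfg$alleles, cfg$alleles),
                            function(a) {
      pc <- campaign$pool_calls
      pc$pool_id[pc$allele == a & pc$positive]
    }),
    n_decoded = vapply(stats::setNames(cfg$alleles, cfg$alleles),
                       function(a) sum(campaign$decoded$allele == a),
                       integer(1)),
    n_confirmed = nrow(campaign$confirmed),
    confirmed = lapply(stats::setNames(cfg$alleles, cfg$alleles),
                       function(a) {
      campaign$confirmed$candidate_id[campaign$confirmed$allele == a]
    }),
    protein_distribution = campaign$characterization$protein_distribution
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    "episcreen campaign log",
    paste0("alleles: ", paste(cfg$alleles, collapse = ", ")),
    paste0("alpha: ", cfg$screen$alpha),
    paste0("floor: ", cfg$screen$floor),
    paste0("test: ", cfg$screen$test),
    paste0("multiplicity: ", cfg$screen$multiplicity),
    if (!is.null(cfg$sim)) paste0("seed: ", cfg$sim$seed),
    paste0("confirmed epitopes: ", nrow(campaign$confirmed))
  )
  writeLines(log_lines, file.path(out_dir, "campaign.log"))
  invisible(out_dir)
}
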