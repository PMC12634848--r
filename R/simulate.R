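# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Small derived seed for independent simulation stages; stays below 2^31.
derive_seed <- function(seed, tag) {
  h <- 0L
  for (code in utf8ToInt(tag)) h <- (h * 131L + code) %% 1000003L
  (as.integer(seed) + h) %% 2147483629L
}

#' Configuration of the synthetic ELISpot campaign
#'
#' Defaults mirror the screening conditions: 4 untreated and 6
#' virus-immunised mice per plate, low background spot counts (mean 10),
#' strong responses to immunogenic stimuli (mean 300, comfortably above the
#' 60-count floor), a ConA positive control around 500 spots, and
#' overdispersed negative-binomial counts. The default dispersion of 20
#' gives a well-to-well coefficient of variation around 23% at 300 spots,
#' typical of replicate ELISpot wells, and separates planted responders
#' cleanly from background.
#'
#' @param seed Integer seed; all simulated randomness derives from it.
#' @param n_control,n_treated Mice per group (defaults 4 and 6).
#' @param background_mean Expected spots for NC/non-immunogenic stimuli.
#' @param dispersion Negative-binomial dispersion (the `size` parameter;
#'   variance = mu + mu^2/size). `Inf` gives Poisson counts.
#' @param effect_mean Expected spots for immunogenic stimuli in treated
#'   mice.
#' @param pc_mean Positive-control mean (both groups respond to ConA).
#' @param true_epitopes Ground-truth immunogenic candidates: character
#'   vector of candidate ids, or a named list keyed by allele.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_control = 4, n_treated = 6,
                              background_mean = 10, dispersion = 20,
                              effect_mean = 300, pc_mean = 500,
                              true_epitopes = list()) {
  stopifnot(n_control >= 2, n_treated >= 2, background_mean > 0,
            dispersion > 0, effect_mean > 0, pc_mean > 0)
  structure(list(seed = as.integer(seed), n_control = as.integer(n_control),
                 n_treated = as.integer(n_treated),
                 background_mean = background_mean, dispersion = dispersion,
                 effect_mean = effect_mean, pc_mean = pc_mean,
                 true_epitopes = true_epitopes),
            class = "simulation_config")
}

true_for_allele <- function(config, allele) {
  te <- config$true_epitopes
  if (is.list(te)) {
    if (!is.null(allele) && !is.na(allele) && allele %in% names(te)) {
      te[[allele]]
    } else if (is.null(names(te))) unlist(te) else character()
  } else {
    as.character(te)
  }
}

rspots <- function(n, mu, dispersion) {
  if (is.infinite(dispersion)) stats::rpois(n, mu)
  else rnbinom(n, size = dispersion, mu = mu)
}

sim_mice <- function(config) {
  tibble::tibble(
    mouse_id = c(sprintf("C%d", seq_len(config$n_control)),
                 sprintf("T%d", seq_len(config$n_treated))),
    group = c(rep("control", config$n_control),
              rep("treated", config$n_treated))
  )
}

#' Simulate a pool-stage ELISpot plate
#'
#' One well per mouse and stimulus (NC, PC, and each pool of the design).
#' Pools containing a planted immunogenic candidate draw from the effect
#' mean in treated mice; control (virus-naive) mice always draw from the
#' background. Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @param design A `pool_design`.
#' @param seed Seed override (default `config$seed`).
#' @return Well tibble: `allele`, `mouse_id`, `group`, `stimulus`, `spots`.
#' @export
simulate_pool_plate <- function(config, design, seed = config$seed) {
  true_ids <- true_for_allele(config, design$allele)
  memb <- pool_membership(design)
  hot_pools <- unique(memb$pool_id[memb$candidate_id %in% true_ids])
  mice <- sim_mice(config)
  grid <- tidyr::expand_grid(
    mice,
    stimulus = c("NC", "PC", paste0("pool:", seq_len(n_pools(design))))
  )
  pool_no <- suppressWarnings(as.integer(parse_stimulus_id(grid$stimulus,
                                                           "pool")))
  mu <- ifelse(
    grid$stimulus == "PC", config$pc_mean,
    ifelse(grid$group == "treated" & !is.na(pool_no) &
             pool_no %in% hot_pools,
           config$effect_mean, config$background_mean)
  )
  spots <- with_seed(seed, rspots(nrow(grid), mu, config$dispersion))
  tibble::tibble(allele = design$allele, mouse_id = grid$mouse_id,
                 group = grid$group, stimulus = grid$stimulus,
                 spots = spots)
}

#' Simulate a single-peptide confirmation plate
#'
#' One well per mouse and candidate peptide (plus NC and PC); planted true
#' epitopes are elevated in treated mice only.
#'
#' @param config A [simulation_config()].
#' @param candidates Character vector of candidate ids to test.
#' @param allele Allele context (used to pick the planted set when
#'   `true_epitopes` is a named list).
#' @param seed Seed override (default `config$seed`).
#' @return Well tibble: `allele`, `mouse_id`, `group`, `stimulus`, `spots`.
#' @export
simulate_peptide_plate <- function(config, candidates, allele = NA_character_,
                                   seed = config$seed) {
  if (length(candidates) == 0) {
    return(tibble::tibble(allele = character(), mouse_id = character(),
                          group = character(), stimulus = character(),
                          spots = integer()))
  }
  true_ids <- true_for_allele(config, allele)
  mice <- sim_mice(config)
  grid <- tidyr::expand_grid(
    mice, stimulus = c("NC", "PC", paste0("peptide:", candidates))
  )
  pep <- parse_stimulus_id(grid$stimulus, "peptide")
  mu <- ifelse(
    grid$stimulus == "PC", config$pc_mean,
    ifelse(grid$group == "treated" & grepl("^peptide:", grid$stimulus) &
             pep %in% true_ids,
           config$effect_mean, config$background_mean)
  )
  spots <- with_seed(seed, rspots(nrow(grid), mu, config$dispersion))
  tibble::tibble(allele = allele, mouse_id = grid$mouse_id,
                 group = grid$group, stimulus = grid$stimulus,
                 spots = spots)
}

#' Configuration of ICS effect structure
#'
#' Multiplicative effects on the IFN-gamma-positive CD8+ frequency:
#' intravenous treatment raises responses relative to intratumoral, and
#' tumor-infiltrating lymphocytes show higher frequencies than splenocytes.
#'
#' @param baseline_freq Background frequency (%, NC wells and untreated
#'   mice).
#' @param epitope_freq Mean frequency (%) for a planted epitope in treated
#'   mice (before route/tissue multipliers).
#' @param pc_freq Positive-control frequency (%).
#' @param route_mult Named multipliers per treated route (default iv = 1,
#'   it = 0.4).
#' @param tissue_mult Named multipliers per tissue (default spleen = 1,
#'   tumor = 3).
#' @param noise_sd Log-normal noise SD on the multiplicative scale.
#' @param stim_route_mult Optional named list: stimulus -> named route
#'   multipliers overriding `route_mult` (used to plant route effects on a
#'   subset of epitopes).
#' @return A list of class `ics_effect_config`.
#' @export
ics_effect_config <- function(baseline_freq = 0.05, epitope_freq = 2,
                              pc_freq = 20,
                              route_mult = c(iv = 1, it = 0.4),
                              tissue_mult = c(spleen = 1, tumor = 3),
                              noise_sd = 0.2, stim_route_mult = NULL) {
  stopifnot(baseline_freq > 0, epitope_freq > 0, pc_freq > 0, noise_sd >= 0)
  structure(list(baseline_freq = baseline_freq, epitope_freq = epitope_freq,
                 pc_freq = pc_freq, route_mult = route_mult,
                 tissue_mult = tissue_mult, noise_sd = noise_sd,
                 stim_route_mult = stim_route_mult),
            class = "ics_effect_config")
}

#' Simulate an ICS frequency table
#'
#' One row per mouse, tissue and stimulus. Untreated mice (route
#' `"untreated"`) and NC wells sit at the background frequency; planted
#' epitope stimuli in treated mice are raised multiplicatively by route and
#' tissue effects. Frequencies are clipped to \[0, 100\].
#'
#' @param config A [simulation_config()] (group sizes and seed).
#' @param effect_config An [ics_effect_config()].
#' @param epitopes Character vector of epitope candidate ids (stimulus
#'   labels become `peptide:<id>`).
#' @param tissues Tissues sampled (default spleen and tumor).
#' @param routes Treated routes (default iv and it); untreated mice are
#'   added as route `"untreated"`.
#' @param seed Seed override (default `config$seed`).
#' @return ICS tibble: `mouse_id`, `group`, `tissue`, `route`, `stimulus`,
#'   `freq_ifng`.
#' @export
simulate_ics <- function(config, effect_config, epitopes,
                         tissues = c("spleen", "tumor"),
                         routes = c("iv", "it"), seed = config$seed) {
  ec <- effect_config
  mice <- list(tibble::tibble(
    mouse_id = sprintf("U%d", seq_len(config$n_control)),
    group = "control", route = "untreated"
  ))
  for (r in routes) {
    mice[[length(mice) + 1L]] <- tibble::tibble(
      mouse_id = sprintf("%s%d", toupper(r), seq_len(config$n_treated)),
      group = "treated", route = r
    )
  }
  mice <- dplyr::bind_rows(mice)
  grid <- tidyr::expand_grid(
    mice, tissue = tissues,
    stimulus = c("NC", "PC", paste0("peptide:", epitopes))
  )
  tm <- ec$tissue_mult[grid$tissue]
  tm[is.na(tm)] <- 1
  rm_ <- ec$route_mult[grid$route]
  rm_[is.na(rm_)] <- 1
  if (!is.null(ec$stim_route_mult)) {
    for (s in names(ec$stim_route_mult)) {
      lab <- if (grepl("^peptide:", s)) s else paste0("peptide:", s)
      ov <- ec$stim_route_mult[[s]][grid$route]
      pick <- grid$stimulus == lab & !is.na(ov)
      rm_[pick] <- ov[pick]
    }
  }
  is_epitope <- grepl("^peptide:", grid$stimulus)
  mu <- ifelse(
    grid$stimulus == "PC", ec$pc_freq * tm,
    ifelse(grid$group == "treated" & is_epitope,
           ec$epitope_freq * rm_ * tm,
           ec$baseline_freq * tm)
  )
  freq <- with_seed(seed, mu * exp(rnorm(nrow(grid), 0, ec$noise_sd)))
  tibble::tibble(mouse_id = grid$mouse_id, group = grid$group,
                 tissue = grid$tissue, route = grid$route,
                 stimulus = grid$stimulus,
                 freq_ifng = pmin(pmax(freq, 0), 100))
}

#' Deterministic synthetic VSV-GP proteome
#'
#' A synthetic stand-in for the five-protein VSV-GP proteome (the real
#' sequences are not redistributed with the package): random 20-letter
#' amino-acid background at realistic protein lengths, with the known
#' reference epitope sequences embedded at fixed positions so that
#' enumeration, location and characterization have true targets to find.
#' The polymerase (L) is truncated to keep desk-scale enumeration light.
#'
#' @return Proteome tibble (`name`, `order_index`, `sequence`) in genome
#'   order.
#' @export
synthetic_proteome <- function() {
  lengths <- c(N = 422L, P = 265L, M = 229L, GP = 498L, L = 600L)
  embed <- list(
    N = list("YMPYLIDFGL" = 51L, "FHFWGQLTAL" = 201L),
    P = list("REYLKSYSRL" = 101L, "FQPKKASLQPL" = 150L, "RAEKSNYEL" = 200L)
  )
  seqs <- with_seed(927215, {
    vapply(names(lengths), function(p) {
      paste(sample(AA_ALPHABET, lengths[[p]], replace = TRUE),
            collapse = "")
    }, character(1))
  })
  for (p in names(embed)) {
    s <- seqs[[p]]
    for (pep in names(embed[[p]])) {
      at <- embed[[p]][[pep]]
      substr(s, at, at + nchar(pep) - 1L) <- pep
    }
    seqs[[p]] <- s
  }
  tibble::tibble(name = names(lengths),
                 order_index = seq_along(lengths),
                 sequence = unname(seqs))
}
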