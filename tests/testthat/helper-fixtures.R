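# Shared fixtures, built in code.

# Minimal panel of n candidates for design tests (ids X1..Xn are arbitrary).
toy_panel <- function(n, allele = "H2-Kd") {
  tibble::tibble(
    allele = allele,
    candidate_id = paste0("X", seq_len(n)),
    rank_index = seq_len(n)
  )
}

# Reference epitopes whose sequences are publicly known.
known_epitopes <- function() {
  e <- validated_epitopes()
  e[!is.na(e$sequence), ]
}

# Deterministic well table for one stimulus.
make_wells <- function(treated, control, stimulus = "pool:1",
                       allele = "H2-Kd") {
  tibble::tibble(
    allele = allele,
    mouse_id = c(paste0("T", seq_along(treated)),
                 paste0("C", seq_along(control))),
    group = c(rep("treated", length(treated)),
              rep("control", length(control))),
    stimulus = stimulus,
    spots = c(treated, control)
  )
}

# Deterministic pool-stage plate: hot pools get strong treated responses,
# everything else sits at background.
make_pool_plate <- function(design, hot_pools,
                            effect = c(300, 310, 290, 305, 295, 300),
                            background = c(8, 12, 10, 9, 11, 10),
                            n_control = 4) {
  plates <- lapply(seq_len(design$n_rows + design$n_cols), function(pid) {
    tr <- if (pid %in% hot_pools) effect else background[seq_along(effect)]
    make_wells(tr, background[seq_len(n_control)],
               stimulus = paste0("pool:", pid), allele = design$allele)
  })
  dplyr::bind_rows(plates)
}

default_truth <- function() {
  split(validated_epitopes()$candidate_id, validated_epitopes()$allele)
}
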