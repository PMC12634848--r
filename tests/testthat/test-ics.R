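test_that("IFN-gamma frequencies are percentages with the 2-decimal convention", {
  expect_equal(ifng_frequency(0, 1000), 0)
  expect_equal(ifng_frequency(50, 1000), 5)
  expect_equal(ifng_frequency(467, 1005), 46.47)
  expect_equal(ifng_frequency(467, 1005, digits = NULL), 100 * 467 / 1005)
  expect_warning(out <- ifng_frequency(0, 0), "undefined")
  expect_true(is.na(out))
  expect_error(ifng_frequency(11, 10), "exceed")
  expect_error(ifng_frequency(-1, 10), "non-negative")
})

test_that("cross-assay correlation matches the closed-form Pearson oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_assays(x, 2 * x)$r, 1)
  expect_equal(correlate_assays(x, -x)$r, -1)
  # fixed 11-point vectors (one per epitope stimulus)
  set.seed(71)
  spots <- c(120, 340, 85, 410, 230, 95, 160, 290, 75, 205, 310)
  freqs <- 0.01 * spots + rnorm(11, 0, 0.4)
  got <- correlate_assays(spots, freqs)
  want <- oracle_pearson(spots, freqs)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  expect_equal(got$n, 11)
  # symmetric and affine-invariant
  expect_equal(correlate_assays(freqs, spots)$r, got$r)
  expect_equal(correlate_assays(3 * spots + 7, freqs / 2 - 1)$r, got$r)
  # degenerate input flagged
  expect_warning(flat <- correlate_assays(rep(2, 5), x), "zero variance")
  expect_true(flat$flagged)
  expect_error(correlate_assays(1:2, 1:2), "at least 3")
})

test_that("route contrasts match a hand-coded Tukey studentized-range oracle", {
  d <- tidyr::expand_grid(stimulus = c("peptide:N1", "peptide:P16"),
                          route = c("iv", "it", "untreated"),
                          mouse = 1:3)
  d$freq_ifng <- c(5.2, 4.8, 5.5, 1.9, 2.2, 2.0, 0.1, 0.2, 0.15,
                   3.1, 3.4, 2.9, 2.8, 3.2, 3.0, 0.1, 0.15, 0.2)
  got <- compare_routes(d)
  want <- oracle_tukey_routes(d)
  for (i in seq_len(nrow(got))) {
    parts <- strsplit(got$contrast[i], " - ")[[1]]
    w <- want[want$stimulus == got$stimulus[i] &
                ((want$a == parts[1] & want$b == parts[2]) |
                   (want$a == parts[2] & want$b == parts[1])), ]
    expect_equal(got$p_value[i], w$p, tolerance = 1e-8)
  }
})

test_that("route comparison recovers exactly the planted iv-over-it stimuli", {
  truth <- validated_epitopes()
  ids <- paste(truth$allele, truth$candidate_id)  # 11 unique stimuli
  boosted <- ids[1:8]
  cfg <- simulation_config(seed = 5L)
  ec <- ics_effect_config(
    route_mult = c(iv = 1, it = 1), noise_sd = 0.05,
    stim_route_mult = stats::setNames(
      lapply(ids, function(s) {
        if (s %in% boosted) c(iv = 3, it = 1) else c(iv = 1, it = 1)
      }), ids)
  )
  ics <- simulate_ics(cfg, ec, ids, tissues = "spleen")
  res <- compare_routes(ics)
  ivit <- res[grepl("^(iv - it|it - iv)$", res$contrast), ]
  expect_equal(nrow(ivit), 11)
  expect_setequal(ivit$stimulus[ivit$significant],
                  paste0("peptide:", boosted))
})

test_that("epitope composition subtracts background, clamps and normalises", {
  ics <- tibble::tibble(
    stimulus = rep(c("A", "B", "C", "NC"), each = 2),
    freq_ifng = c(2.4, 1.6, 2.2, 1.8, 1.1, 0.9, 0, 0)
  )
  comp <- epitope_composition(ics, c("A", "B", "C"))
  expect_equal(comp$summary$proportion, c(0.4, 0.4, 0.2))
  expect_equal(sum(comp$summary$proportion), 1)
  # single epitope takes the whole pie
  single <- epitope_composition(ics[ics$stimulus %in% c("A", "NC"), ], "A")
  expect_equal(single$summary$proportion, 1)
  # NC above an epitope clamps that epitope to zero before normalising
  ics2 <- ics
  ics2$freq_ifng[ics2$stimulus == "NC"] <- 1.5
  comp2 <- epitope_composition(ics2, c("A", "B", "C"))
  expect_equal(comp2$summary$adjusted_mean[3], 0)
  expect_equal(sum(comp2$summary$proportion), 1)
  # all-zero signal flagged with undefined proportions
  ics3 <- ics
  ics3$freq_ifng <- 0
  expect_warning(comp3 <- epitope_composition(ics3, c("A", "B", "C")),
                 "undefined")
  expect_true(comp3$flagged)
  expect_true(all(is.na(comp3$summary$proportion)))
})

test_that("polyfunctionality gates are count ratios summing to 100 percent", {
  combos <- expand.grid(ifng = c(FALSE, TRUE), tnfa = c(FALSE, TRUE),
                        cd107a = c(FALSE, TRUE))
  combos$count <- c(900, 40, 0, 0, 30, 25, 0, 5)
  gates <- polyfunction_gates(combos, total = 1000)
  expect_equal(gates$combinations$freq,
               100 * combos$count / 1000)
  expect_equal(sum(gates$combinations$freq), 100, tolerance = 1e-9)
  expect_equal(sum(gates$classes$freq), 100, tolerance = 1e-9)
  # TNF-alpha channel all-negative: no triple positives
  expect_equal(gates$classes$freq[gates$classes$class == "triple"], 0.5)
  no_tnf <- combos
  no_tnf$count <- c(900, 60, 0, 0, 35, 5, 0, 0)
  gates2 <- polyfunction_gates(no_tnf)
  expect_equal(gates2$classes$freq[gates2$classes$class == "triple"], 0)
  # all events in the null combination: all marker gates at zero
  null_only <- combos
  null_only$count <- c(1000, rep(0, 7))
  gates3 <- polyfunction_gates(null_only)
  expect_equal(sum(gates3$classes$freq[gates3$classes$class != "none"]), 0)
  # counts must reconcile with the stated total
  expect_error(polyfunction_gates(combos, total = 999), "do not sum")
  expect_error(polyfunction_gates(combos[-1, ]), "8 marker combinations")
})
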