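test_that("binder tiers follow the percent-rank thresholds, boundaries to the weaker tier", {
  expect_identical(
    tier_binders(c(0.1, 0.49, 0.5, 1.9, 2.0, 9.9, 10, 50)),
    c("strong", "strong", "weak", "weak", "marginal", "marginal",
      "non", "non")
  )
  expect_error(tier_binders(NA_real_), "missing")
  # monotone: a lower percent rank never yields a weaker tier
  set.seed(41)
  pr <- sort(runif(200, 0, 20))
  ord <- match(tier_binders(pr), c("strong", "weak", "marginal", "non"))
  expect_true(all(diff(ord) >= 0))
})

test_that("surrogate scores are deterministic and reward anchor-motif matches", {
  a <- surrogate_score("EYLKSYSRL", "H2-Kd")
  b <- surrogate_score("EYLKSYSRL", "H2-Kd")
  expect_identical(a, b)
  # both anchors matched beats none matched
  worse <- surrogate_score("EALKSYSRA", "H2-Kd")
  expect_lt(a$percent_rank, worse$percent_rank)
  expect_lt(a$affinity_nM, worse$affinity_nM)
  # H2-Ld position-2 proline anchor
  expect_lt(surrogate_score("MPYLIDFGL", "H2-Ld")$percent_rank,
            surrogate_score("MAYLIDFGL", "H2-Ld")$percent_rank)
  # mutating position 2 to the H2-Kd anchor strictly improves the rank
  set.seed(42)
  aa <- strsplit("ACDEFGHIKMNPQRSTVW", "")[[1]]  # no Y, no L/I
  for (i in 1:20) {
    pep <- paste(sample(aa, 9, replace = TRUE), collapse = "")
    mut <- pep
    substr(mut, 2, 2) <- "Y"
    expect_lt(surrogate_score(mut, "H2-Kd")$percent_rank,
              surrogate_score(pep, "H2-Kd")$percent_rank)
  }
  expect_error(surrogate_score("EYLKSYSRL", "H2-Xx"), "unknown allele")
  expect_error(surrogate_score("SHORT", "H2-Kd"), "8-11")
})

test_that("score tables load, tier and flag unscored peptides", {
  tab <- tibble::tibble(
    peptide = "EYLKSYSRL", allele = "H2-Kd",
    affinity_nM = 25.0, percent_rank = 0.1,
    stability = 2.5, immunogenicity = 0.3
  )
  sc <- load_scores(tab)
  expect_identical(sc$tier, "strong")
  # empty table: whole universe unscored
  empty <- load_scores(tab[0, ], universe = c("AAAAAAAA", "CCCCCCCC"))
  expect_equal(nrow(empty), 2)
  expect_false(any(empty$scored))
  # negative affinity rejected
  expect_error(load_scores(dplyr::mutate(tab, affinity_nM = -5)),
               "affinity")
  expect_error(load_scores(tab[, -1]), "missing column")
  # round trip through a TSV file
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tab, path)
  expect_equal(load_scores(path)$percent_rank, 0.1)
})

test_that("default panel selection yields 50 candidates in quota blocks with scheme ids", {
  windows <- enumerate_peptides(synthetic_proteome())
  for (allele in balbc_alleles()) {
    panel <- select_panel(score_universe(windows, allele), allele)
    expect_equal(nrow(panel), 50)
    counts <- table(panel$protein)[c("N", "P", "M", "GP", "L")]
    expect_equal(unname(as.integer(counts)), c(15, 15, 10, 5, 5))
    # ids are protein letter + global index; blocks partition 1..50
    expect_identical(panel$candidate_id,
                     paste0(c(N = "N", P = "P", M = "M", GP = "G",
                              L = "L")[panel$protein], 1:50))
    expect_identical(panel$candidate_id[16], "P16")
    expect_identical(panel$rank_index, 1:50)
    expect_false(anyDuplicated(panel$sequence) > 0)
    # deterministic
    expect_identical(panel,
                     select_panel(score_universe(windows, allele), allele))
  }
})

test_that("duplicate sequences are attributed to the earlier protein once", {
  pro <- synthetic_proteome()
  # copy a stretch of N into L so identical windows exist in both
  substr(pro$sequence[5], 101, 130) <- substr(pro$sequence[1], 101, 130)
  windows <- enumerate_peptides(pro)
  dup_peps <- windows$peptide[windows$protein == "L" &
                                windows$start >= 101 & windows$start <= 120]
  panel <- select_panel(score_universe(windows, "H2-Kd"), "H2-Kd")
  in_panel <- panel[panel$sequence %in% dup_peps, ]
  expect_true(all(in_panel$protein == "N"))
  expect_false(anyDuplicated(panel$sequence) > 0)
})

test_that("quota shortfall cascades forward in genome order with a warning", {
  pro <- synthetic_proteome()
  pro$sequence[3] <- substr(pro$sequence[3], 1, 9)  # M yields 2+1 windows
  windows <- enumerate_peptides(pro)
  expect_warning(
    panel <- select_panel(score_universe(windows, "H2-Kd"), "H2-Kd"),
    "cascading"
  )
  expect_equal(nrow(panel), 50)
  counts <- table(panel$protein)
  expect_equal(unname(counts[["M"]]), 3)
  expect_equal(unname(counts[["GP"]]), 12)  # 5 + 7 cascaded slots
  expect_identical(panel$candidate_id,
                   paste0(c(N = "N", P = "P", M = "M", GP = "G",
                            L = "L")[panel$protein], 1:50))
})

test_that("a zero budget yields an empty panel", {
  windows <- enumerate_peptides(synthetic_proteome())
  scheme <- c(N = 0, P = 0, M = 0, GP = 0, L = 0)
  panel <- select_panel(score_universe(windows, "H2-Kd"), "H2-Kd", scheme)
  expect_equal(nrow(panel), 0)
  expect_error(allocation_scheme(c(N = 5, P = 15, M = 10, GP = 5, L = 5)),
               "non-increasing")
})
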