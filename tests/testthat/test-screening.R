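test_that("plate QC checks controls against floor and background ceiling", {
  good <- dplyr::bind_rows(make_wells(c(400, 420), c(380, 400), "PC"),
                           make_wells(c(5, 6), c(4, 7), "NC"))
  expect_true(qc_plate(good)$pass)
  # positive control below the 60-count floor
  weak_pc <- dplyr::bind_rows(make_wells(c(30, 25), c(28, 31), "PC"),
                              make_wells(c(5, 6), c(4, 7), "NC"))
  qc <- qc_plate(weak_pc)
  expect_false(qc$pass)
  expect_true(any(grepl("positive control below floor",
                        qc$checks$reason)))
  # missing negative control
  no_nc <- make_wells(c(400, 420), c(380, 400), "PC")
  qc2 <- qc_plate(no_nc)
  expect_false(qc2$pass)
  expect_true(any(grepl("missing negative control", qc2$checks$reason)))
})

test_that("positivity calls match an independent t-test oracle", {
  tr <- c(200, 220, 210, 190)
  ct <- c(5, 8, 6, 7)
  call <- call_stimulus(make_wells(tr, ct))
  expect_true(call$positive)
  expect_equal(call$p_value, oracle_t_p(tr, ct), tolerance = 1e-10)
  # Welch variant against its own oracle
  callw <- call_stimulus(make_wells(tr, ct),
                         screen_config(test = "welch"))
  expect_equal(callw$p_value, oracle_t_p(tr, ct, equal_var = FALSE),
               tolerance = 1e-10)
  # random inputs, both variants
  set.seed(61)
  for (i in 1:20) {
    x <- rpois(sample(3:8, 1), 100)
    y <- rpois(sample(3:8, 1), 40)
    expect_equal(call_stimulus(make_wells(x, y))$p_value,
                 oracle_t_p(x, y), tolerance = 1e-10)
  }
})

test_that("the positivity rule needs significance, the floor and a treated excess", {
  # identical groups: no effect
  expect_false(call_stimulus(make_wells(c(100, 110, 105), c(100, 110, 105)))$positive)
  # constant identical data: indeterminate evidence, never positive
  expect_false(call_stimulus(make_wells(c(5, 5), c(5, 5)))$positive)
  # significant but below the 60-count floor
  floor_call <- call_stimulus(make_wells(c(55, 58, 57, 56), c(5, 6, 5, 7)))
  expect_lt(floor_call$p_value, 0.05)
  expect_false(floor_call$passes_floor)
  expect_false(floor_call$positive)
  # fewer than two wells in a group: indeterminate, not positive
  solo <- call_stimulus(make_wells(300, c(5, 6, 7)))
  expect_true(solo$indeterminate)
  expect_false(solo$positive)
  # control exceeding treated can never be positive
  expect_false(call_stimulus(make_wells(c(70, 75, 72), c(300, 310, 305)))$positive)
})

test_that("pool calling finds exactly the planted pools and splits orientation", {
  design <- build_matrix(toy_panel(50))
  hot <- c(1:4, 8:12)
  plate <- make_pool_plate(design, hot)
  res <- call_pools(plate, design)
  expect_identical(res$positive_pools, hot)
  expect_identical(res$positive_horizontal, 1:4)
  expect_identical(res$positive_vertical, 8:12)
  expect_equal(nrow(res$calls), 14)
  # plate with a pool missing -> that pool indeterminate
  res2 <- call_pools(plate[plate$stimulus != "pool:14", ], design)
  expect_true(res2$calls$indeterminate[res2$calls$pool_id == 14])
  expect_false(14 %in% res2$positive_pools)
  # all pools planted -> all positive
  res3 <- call_pools(make_pool_plate(design, 1:14), design)
  expect_identical(res3$positive_pools, 1:14)
})

test_that("single-peptide confirmation recovers planted responders only", {
  candidates <- paste0("X", 1:20)
  planted <- c("X1", "X5", "X9", "X12", "X20")
  wells <- dplyr::bind_rows(lapply(candidates, function(id) {
    tr <- if (id %in% planted) c(280, 300, 310, 290) else c(9, 11, 10, 12)
    make_wells(tr, c(10, 9, 12, 8), paste0("peptide:", id))
  }))
  conf <- confirm_peptides(wells, candidates)
  expect_setequal(conf$candidate_id[conf$elispot_confirmed], planted)
  # zero candidates
  expect_equal(nrow(confirm_peptides(wells, character())), 0)
  # planted effect below the floor confirms nothing
  low <- dplyr::bind_rows(lapply(candidates[1:3], function(id) {
    make_wells(c(40, 45, 42, 44), c(5, 6, 5, 7), paste0("peptide:", id))
  }))
  conf_low <- confirm_peptides(low, candidates[1:3])
  expect_false(any(conf_low$elispot_confirmed))
  # a candidate without wells is left unconfirmed with a warning
  expect_warning(
    conf_miss <- confirm_peptides(wells, c("X1", "X99")),
    "X99.*no single-peptide wells"
  )
  expect_false(conf_miss$elispot_confirmed[conf_miss$candidate_id == "X99"])
})

test_that("the two-stage screen nests confirmed within decoded within panel", {
  windows <- enumerate_peptides(synthetic_proteome())
  panel <- select_panel(score_universe(windows, "H2-Kd"), "H2-Kd")
  design <- build_matrix(panel)
  truth <- c("N6", "N7", "N8", "P16", "P25")
  cfg <- simulation_config(seed = 7L, true_epitopes = truth)
  pool_wells <- simulate_pool_plate(cfg, design)
  dec <- decode(design, call_pools(pool_wells, design)$positive_pools)
  pep_wells <- simulate_peptide_plate(cfg, dec$candidates,
                                      allele = "H2-Kd", seed = 8L)
  res <- two_stage_screen(pool_wells, pep_wells, design, panel)
  expect_true(all(res$confirmed$candidate_id %in% res$decoded$candidate_id))
  expect_true(all(res$decoded$candidate_id %in% panel$candidate_id))
  expect_setequal(res$confirmed$candidate_id, truth)
  # stage separation: absent stage-2 wells leave decoded intact, confirmed empty
  res2 <- two_stage_screen(pool_wells, NULL, design, panel)
  expect_equal(nrow(res2$decoded), 20)
  expect_equal(nrow(res2$confirmed), 0)
})
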