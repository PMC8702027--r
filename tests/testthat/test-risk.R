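mini_lineage <- tibble::tibble(
  analyte = c("pahA", "C1_pahA", "C2_pahA", "pahB", "total"),
  parent = c(NA, "pahA", "pahA", NA, NA),
  is_total = c(FALSE, FALSE, FALSE, FALSE, TRUE),
  fraction = c(NA, 0.5, 0.5, NA, NA), base_log10 = NA_real_
)

mini_params <- tibble::tibble(
  parent = rep(c("pahA", "pahB"), 2),
  scenario = rep(c("recreational_sediment", "residential_soil"), each = 2),
  sl_nc = c(100, 200, 10, 20),
  sl_ca = c(50, 400, 5, 40)
)

test_that("alkylated homologs are summed into parents, totals excluded", {
  chem <- tibble::tibble(sample_id = "s1", pahA = 10, C1_pahA = 5,
                         C2_pahA = 5, pahB = 7, total = 27)
  prof <- aggregate_alkylated(chem, mini_lineage)
  expect_equal(prof$concentration[prof$parent == "pahA"], 20)
  expect_equal(prof$concentration[prof$parent == "pahB"], 7)
  # conservation: effective parents account for every non-total analyte
  expect_equal(sum(prof$concentration), 27)
})

test_that("aggregation conserves mass on a random synthetic profile", {
  d <- small_design()
  chem <- generate_chemistry(generate_sites(d, 19), d, 19)$chemistry
  prof <- aggregate_alkylated(chem, d$analytes)
  nt <- d$analytes$analyte[!d$analytes$is_total]
  tot <- dplyr::summarise(dplyr::group_by(prof, sample_id),
                          s = sum(concentration))
  expect_equal(tot$s[match(chem$sample_id, tot$sample_id)],
               unname(rowSums(chem[nt])), tolerance = 1e-9)
  # conservative: effective parent >= raw parent
  parents <- d$analytes$analyte[is.na(d$analytes$parent) & !d$analytes$is_total]
  for (p in parents[1:4]) {
    sub <- prof[prof$parent == p, ]
    eff <- sub$concentration[match(chem$sample_id, sub$sample_id)]
    expect_true(all(eff >= chem[[p]]))
  }
})

test_that("HI and CR hit their defining anchors exactly", {
  chem0 <- tibble::tibble(sample_id = "s", pahA = 0, pahB = 0)
  r0 <- risk_assess(chem0, mini_params, "recreational_sediment", mini_lineage)
  expect_equal(r0$HI, 0)
  expect_equal(r0$CR, 0)
  # one PAH at its screening level
  chem1 <- tibble::tibble(sample_id = "s", pahA = 100, pahB = 0)
  r1 <- risk_assess(chem1, mini_params, "recreational_sediment", mini_lineage)
  expect_equal(r1$HI, 1)
  chem2 <- tibble::tibble(sample_id = "s", pahA = 50, pahB = 0)
  r2 <- risk_assess(chem2, mini_params, "recreational_sediment", mini_lineage)
  expect_equal(r2$CR, 1)
})

test_that("HI sums hazard quotients and both metrics are exactly linear", {
  params3 <- tibble::tibble(parent = c("a", "b", "c"),
                            scenario = "recreational_sediment",
                            sl_nc = c(10, 20, 40), sl_ca = c(1, 1, 1))
  lin3 <- tibble::tibble(analyte = c("a", "b", "c"), parent = NA_character_,
                         is_total = FALSE, fraction = NA_real_,
                         base_log10 = NA_real_)
  chem <- tibble::tibble(sample_id = "s", a = 5, b = 5, c = 10)
  r <- risk_assess(chem, params3, "recreational_sediment", lin3)
  expect_equal(r$HI, 0.5 + 0.25 + 0.25)
  r2 <- risk_assess(dplyr::mutate(chem, a = 2 * a, b = 2 * b, c = 2 * c),
                    params3, "recreational_sediment", lin3)
  expect_equal(r2$HI, 2 * r$HI)
  expect_equal(r2$CR, 2 * r$CR)
})

test_that("the residential scenario dominates the recreational one", {
  d <- small_design()
  chem <- generate_chemistry(generate_sites(d, 23), d, 23)$chemistry
  r <- risk_assess(chem)
  wide <- tidyr::pivot_wider(r, names_from = scenario,
                             values_from = c(HI, CR))
  expect_true(all(wide$HI_residential_soil >= wide$HI_recreational_sediment))
  expect_true(all(wide$CR_residential_soil >= wide$CR_recreational_sediment))
})

test_that("missing screening levels are skipped with a warning or error", {
  chem <- tibble::tibble(sample_id = "s", pahA = 10, pahB = 5, pahC = 3)
  lin <- dplyr::bind_rows(mini_lineage[c(1, 4), ],
                          tibble::tibble(analyte = "pahC",
                                         parent = NA_character_,
                                         is_total = FALSE, fraction = NA_real_,
                                         base_log10 = NA_real_))
  expect_warning(r <- risk_assess(chem, mini_params,
                                  "recreational_sediment", lin), "pahC")
  expect_equal(r$HI, 10 / 100 + 5 / 200)
  expect_error(risk_assess(chem, mini_params, "recreational_sediment", lin,
                           on_missing = "error"), "pahC")
})

test_that("the shipped screening-level table is complete and positive", {
  params <- default_tox_params()
  parents <- default_analytes()
  parents <- parents$analyte[is.na(parents$parent) & !parents$is_total]
  for (sc in c("recreational_sediment", "residential_soil")) {
    expect_setequal(params$parent[params$scenario == sc], parents)
  }
  expect_true(all(params$sl_nc > 0 & params$sl_ca > 0))
})
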