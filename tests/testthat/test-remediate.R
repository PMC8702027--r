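test_that("the traditional factor is the max of HI, CR and 1", {
  expect_equal(traditional_goal(0.5, 0.2), 1)
  expect_equal(traditional_goal(0.5, 5), 5)
  expect_equal(traditional_goal(3, 2), 3)
  expect_equal(traditional_goal(c(0.5, 3), c(5, 2)), c(5, 3))
  # post-remediation compliance by linearity
  expect_equal(5 / traditional_goal(0.5, 5), 1)
  expect_equal(c(3, 2) / traditional_goal(3, 2), c(1, 2 / 3))
  expect_error(traditional_goal(-1, 0), "nonnegative")
})

test_that("fraction_active counts endpoints by the POD threshold rule", {
  pods <- dplyr::bind_rows(
    pods_tbl("s", sprintf("a%d", 1:5), c(0.01, 0.03, 0.1, 0.3, 0.9)),
    pods_tbl("s", sprintf("c%d", 1:5), 1, censored = TRUE)
  )
  expect_equal(fraction_active(pods, 0.005)$fraction_active, 0)
  # between the 2nd and 3rd smallest POD -> 2 of 10 active
  expect_equal(fraction_active(pods, 0.05)$fraction_active, 0.2)
  expect_equal(fraction_active(pods, 1)$fraction_active, 0.5)
  all_active <- pods_tbl("s", sprintf("a%d", 1:4), c(0.1, 0.2, 0.5, 1))
  expect_equal(fraction_active(all_active, 1)$fraction_active, 1)
  expect_error(fraction_active(pods, 0), "dilution")
})

test_that("the bioactivity goal matches the interpolated percentile and the scan oracle", {
  pods <- pods_tbl("s", sprintf("e%d", 1:10), 0.01 * (1:10))
  bg <- bioactivity_goal(pods)
  # type-7 10th percentile of 10 PODs
  expect_equal(bg$goal_dilution, unname(quantile(0.01 * (1:10), 0.1)))
  expect_equal(bg$goal_dilution, 0.019)
  expect_equal(bg$bioactivity_factor, 1 / 0.019)
  # scan oracle: compliance first holds at the returned goal scanning down
  scan <- 10^seq(0, -3, by = -1e-3)
  frac <- vapply(scan, function(d) mean(d >= pods$pod), numeric(1))
  first_ok <- scan[which(frac <= 0.10)[1]]
  expect_lte(mean(bg$goal_dilution >= pods$pod), 0.10)
  expect_lte(bg$goal_dilution, first_ok)
})

test_that("the goal is capped just below the POD that would breach 10%", {
  # 34 distinct PODs: floor(0.1 * 34) = 3 active allowed; the interpolated
  # percentile would sit on the 4th order statistic and allow 4
  pods <- pods_tbl("s", sprintf("e%d", 1:34), 0.01 * (1:34))
  bg <- bioactivity_goal(pods)
  fr <- fraction_active(pods, bg$goal_dilution)$fraction_active
  expect_lte(fr, 0.10)
  # boundary tightness: epsilon more dilution breaches the bound
  fr_eps <- fraction_active(pods, bg$goal_dilution * (1 + 1e-6))$fraction_active
  expect_gt(fr_eps, 0.10)
})

test_that("censored endpoints enter the denominator but never the percentile", {
  pods <- dplyr::bind_rows(
    pods_tbl("s", sprintf("a%d", 1:2), c(0.01, 0.02)),
    pods_tbl("s", sprintf("c%d", 1:18), 1, censored = TRUE)
  )
  # 2/20 active at baseline -> already compliant
  bg <- bioactivity_goal(pods)
  expect_equal(bg$goal_dilution, 1)
  expect_equal(bg$bioactivity_factor, 1)
})

test_that("fully censored samples need no remediation", {
  pods <- pods_tbl("s", sprintf("c%d", 1:8), 1, censored = TRUE)
  bg <- bioactivity_goal(pods)
  expect_equal(bg$bioactivity_factor, 1)
  expect_equal(nrow(bioactivity_goal(pods[0, ])), 0)
})

test_that("residuals follow the linear-scaling identities", {
  pods <- pods_tbl("s1", sprintf("e%d", 1:10), c(seq(0.01, 0.05, by = 0.01),
                                                 rep(0.8, 5)))
  risk <- tibble::tibble(sample_id = "s1", scenario = "recreational_sediment",
                         HI = 0.5, CR = 5)
  rem <- remediation_table(risk, pods)
  expect_equal(rem$traditional_factor, 5)
  expect_equal(rem$residual_CR_after_bioactivity,
               5 / rem$bioactivity_factor)
  expect_equal(rem$residual_HI_after_bioactivity,
               0.5 / rem$bioactivity_factor)
  # traditional factor 1 leaves the baseline fraction untouched
  risk1 <- tibble::tibble(sample_id = "s1", scenario = "recreational_sediment",
                          HI = 0.2, CR = 0.3)
  rem1 <- remediation_table(risk1, pods)
  expect_equal(rem1$traditional_factor, 1)
  expect_equal(rem1$residual_fraction_active_after_traditional,
               rem1$baseline_fraction_active)
})

test_that("remediation guarantees hold exactly on a simulated study", {
  d <- small_design()
  st <- simulate_study(d, seed = 29)
  pods <- truth_pods_tbl(st)
  risk <- dplyr::filter(risk_assess(st$chemistry),
                        scenario == "recreational_sediment")
  rem <- remediation_table(risk, pods)
  expect_true(all(rem$traditional_factor >= 1))
  expect_true(all(rem$bioactivity_factor >= 1))
  expect_true(all(rem$HI / rem$traditional_factor <= 1 + 1e-12))
  expect_true(all(rem$CR / rem$traditional_factor <= 1 + 1e-12))
  expect_true(all(rem$fraction_active_after_bioactivity <= 0.10))
  # residual risk is monotone non-increasing in the remediation factor
  expect_true(all(rem$residual_CR_after_bioactivity <= rem$CR + 1e-12))
})

test_that("the dumbbell table pairs baselines with cross-criterion residuals", {
  pods <- pods_tbl("s1", sprintf("e%d", 1:5), c(0.01, 0.1, 0.2, 0.5, 1))
  risk <- tibble::tibble(sample_id = "s1", scenario = "recreational_sediment",
                         HI = 2, CR = 3)
  db <- remediation_dumbbell(remediation_table(risk, pods))
  expect_equal(nrow(db), 2)
  expect_setequal(db$panel, c("bioactivity", "cancer_risk"))
  expect_equal(db$target, c(0.10, 1))
  expect_equal(db$baseline[db$panel == "cancer_risk"], 3)
})
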