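#' Fraction of bioactive endpoints at a given dilution
#'
#' An endpoint is counted active at dilution `d` when it is not censored and
#' `d >= POD`; the fraction is over all endpoints of the sample (censored
#' endpoints stay in the denominator).
#'
#' @param pods POD tibble (`sample_id`, `endpoint_id`, `pod`, `censored`).
#' @param dilution Dilution fraction of extract stock, in (0, 1].
#' @return A tibble `sample_id`, `dilution`, `fraction_active`.
#' @export
fraction_active <- function(pods, dilution = 1) {
  assert_that(all(dilution > 0 & dilution <= 1),
              "dilution must lie in (0, 1]")
  purrr::map_dfr(dilution, function(d) {
    pods |>
      dplyr::group_by(sample_id) |>
      dplyr::summarise(
        dilution = d,
        fraction_active = mean(!censored & d >= pod),
        .groups = "drop"
      )
  })
}

#' Traditional remediation factor from HI and CR
#'
#' The fold-reduction in concentration needed to satisfy `HI <= 1` and
#' `CR <= 1` per million. Because both metrics are linear in concentration,
#' the factor is `max(HI, CR, 1)` (CR already in per-million units);
#' already-compliant samples get factor 1.
#'
#' @param HI,CR Numeric vectors (CR in cases per million).
#' @return Numeric vector of fold-reductions, all `>= 1`.
#' @export
traditional_goal <- function(HI, CR) {
  assert_that(all(HI >= 0) && all(CR >= 0), "HI and CR must be nonnegative")
  pmax(HI, CR, 1)
}

# interpolated (type-7) quantile of a pool that may contain +Inf entries,
# computed so that a zero interpolation weight never touches the upper
# order statistic (0 * Inf would be NaN)
quantile7_inf <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  j <- floor(h)
  g <- h - j
  if (g == 0 || j >= n) return(x[j])
  if (is.infinite(x[j + 1])) return(Inf)
  x[j] + g * (x[j + 1] - x[j])
}

#' Bioactivity-based remediation goal per sample
#'
#' The goal dilution at which no more than 10% of the sample's endpoints are
#' bioactive. Nominally the 10th percentile (type-7, linear interpolation)
#' of the sample's POD pool, with censored endpoints contributing `+Inf`
#' (never active at any tested dilution) while remaining in the denominator
#' of the active fraction. Because the interpolated percentile can sit
#' exactly on (or just above) the POD whose activation would breach the 10%
#' bound, the goal is additionally capped just below that POD, making the
#' protectiveness guarantee `fraction_active(goal) <= 0.10` exact. Samples
#' already at or below 10% active need no remediation (goal 1, factor 1).
#' The remediation factor is `baseline / goal` with baseline = undiluted
#' extract (1.0), floored at 1.
#'
#' @param pods POD tibble for one or more samples.
#' @param max_frac Maximum allowed active fraction (default 0.10).
#' @return A tibble `sample_id`, `goal_dilution`, `bioactivity_factor`.
#' @export
bioactivity_goal <- function(pods, max_frac = 0.10) {
  if (nrow(pods) == 0) {
    return(tibble::tibble(sample_id = character(), goal_dilution = numeric(),
                          bioactivity_factor = numeric()))
  }
  pods |>
    dplyr::group_by(sample_id) |>
    dplyr::group_modify(function(df, key) {
      assert_that(nrow(df) >= 1, "no PODs for sample")
      pool <- ifelse(df$censored, Inf, df$pod)
      n <- length(pool)
      m <- floor(max_frac * n)  # largest allowed number of active endpoints
      fin <- sort(pool[is.finite(pool)])
      if (length(fin) <= m) {
        return(tibble::tibble(goal_dilution = 1, bioactivity_factor = 1))
      }
      q <- quantile7_inf(pool, max_frac)
      cap <- fin[m + 1] * (1 - 1e-9)
      goal <- min(q, cap, 1)
      tibble::tibble(goal_dilution = goal,
                     bioactivity_factor = max(1, 1 / goal))
    }) |>
    dplyr::ungroup()
}

#' Compare traditional and bioactivity-based remediation goals
#'
#' For every sample, computes the traditional (risk-based) remediation
#' factor from HI and CR, the bioactivity-based goal dilution and factor
#' from the PODs, and the residuals that reveal how protective each approach
#' is of the other metric: the fraction of endpoints still active after
#' traditional remediation (evaluated at dilution `1 / traditional_factor`)
#' and the cancer risk and hazard index remaining after bioactivity-based
#' remediation (`CR / factor`, `HI / factor`).
#'
#' @param risk Risk tibble from [risk_assess()], one scenario
#'   (`sample_id`, `HI`, `CR`).
#' @param pods POD tibble covering the same samples.
#' @param max_frac Bioactivity goal threshold (default 0.10).
#' @return A `sed_remediation` tibble: `sample_id`, `HI`, `CR`,
#'   `traditional_factor`, `goal_dilution`, `bioactivity_factor`,
#'   `baseline_fraction_active`, `residual_fraction_active_after_traditional`,
#'   `fraction_active_after_bioactivity`, `residual_CR_after_bioactivity`,
#'   `residual_HI_after_bioactivity`.
#' @export
remediation_table <- function(risk, pods, max_frac = 0.10) {
  assert_that(length(unique(risk$scenario %||% "x")) == 1,
              "risk must contain a single scenario")
  bio <- bioactivity_goal(pods, max_frac = max_frac)
  base <- fraction_active(pods, 1) |>
    dplyr::select(sample_id, baseline_fraction_active = fraction_active)
  out <- risk |>
    dplyr::select(sample_id, HI, CR) |>
    dplyr::mutate(traditional_factor = traditional_goal(HI, CR)) |>
    dplyr::left_join(bio, by = "sample_id") |>
    dplyr::left_join(base, by = "sample_id")
  assert_that(!anyNA(out$goal_dilution),
              "pods must cover every sample in the risk table")
  resid_trad <- purrr::map2_dbl(out$sample_id, out$traditional_factor,
    function(sid, f) {
      fraction_active(pods[pods$sample_id == sid, ], 1 / f)$fraction_active
    })
  resid_bio_frac <- purrr::map2_dbl(out$sample_id, out$bioactivity_factor,
    function(sid, f) {
      fraction_active(pods[pods$sample_id == sid, ], 1 / f)$fraction_active
    })
  out <- out |>
    dplyr::mutate(
      residual_fraction_active_after_traditional = resid_trad,
      fraction_active_after_bioactivity = resid_bio_frac,
      residual_CR_after_bioactivity = CR / bioactivity_factor,
      residual_HI_after_bioactivity = HI / bioactivity_factor
    )
  structure(out, class = c("sed_remediation", class(out)))
}

#' Long-format dumbbell table for remediation comparison
#'
#' One row per sample and panel, pairing the baseline value with the value
#' after the *other* criterion's remediation: panel `bioactivity` shows the
#' active fraction before and after traditional (risk-based) remediation
#' (target 0.10); panel `cancer_risk` shows CR per million before and after
#' bioactivity-based remediation (target 1).
#'
#' @param rem A [remediation_table()] result.
#' @return A tibble `sample_id`, `panel`, `baseline`, `remediated`,
#'   `target`, `meets_target`.
#' @export
remediation_dumbbell <- function(rem) {
  dplyr::bind_rows(
    tibble::tibble(
      sample_id = rem$sample_id, panel = "bioactivity",
      baseline = rem$baseline_fraction_active,
      remediated = rem$residual_fraction_active_after_traditional,
      target = 0.10
    ),
    tibble::tibble(
      sample_id = rem$sample_id, panel = "cancer_risk",
      baseline = rem$CR,
      remediated = rem$residual_CR_after_bioactivity,
      target = 1
    )
  ) |>
    dplyr::mutate(meets_target = remediated <= target)
}
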