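#' Illustrative screening-level parameter table
#'
#' Loads the screening levels shipped with the package:
#' per parent PAH and exposure scenario, the non-cancer screening level
#' `sl_nc` (ng/g at hazard quotient 1) and the cancer screening level
#' `sl_ca` (ng/g at 1e-6 risk). Two scenarios are provided: recreational
#' sediment contact (short, infrequent exposure) and residential soil
#' (sediment deposited on land; continuous exposure). The shipped values are
#' synthetic/illustrative (the residential levels are the recreational ones
#' divided by a 280-fold exposure-duration ratio, 350 d x 24 h vs
#' 5 d x 6 h); authoritative, versioned screening levels must be supplied by
#' the user for any real assessment.
#'
#' @param path Optional path to a CSV with columns `parent`, `scenario`,
#'   `sl_nc`, `sl_ca` to use instead of the shipped illustrative table.
#' @return A tibble `parent`, `scenario`, `sl_nc`, `sl_ca`.
#' @export
default_tox_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "screening_levels_synthetic.csv",
                        package = "sedscreen")
  }
  out <- readr::read_csv(path, show_col_types = FALSE)
  assert_that(all(c("parent", "scenario", "sl_nc", "sl_ca") %in% names(out)),
              "screening-level table needs parent, scenario, sl_nc, sl_ca")
  assert_that(all(out$sl_nc > 0) && all(out$sl_ca > 0),
              "all screening levels must be positive")
  out
}

#' Sum alkylated homologs into their parent PAHs
#'
#' Conservative aggregation for risk screening: each parent's effective
#' concentration is the parent concentration plus the sum of its alkylated
#' homologs. Total columns are excluded from the summation.
#'
#' @param chemistry Wide chemistry tibble (`sample_id` + analyte columns).
#' @param lineage Analyte lineage table (`analyte`, `parent`, `is_total`),
#'   default [default_analytes()].
#' @return A long tibble `sample_id`, `parent`, `concentration` (ng/g).
#' @export
aggregate_alkylated <- function(chemistry, lineage = default_analytes()) {
  lineage <- lineage[lineage$analyte %in% names(chemistry), ]
  nt <- lineage[!lineage$is_total, ]
  nt$group <- ifelse(is.na(nt$parent), nt$analyte, nt$parent)
  chemistry |>
    dplyr::select(sample_id, dplyr::all_of(nt$analyte)) |>
    tidyr::pivot_longer(-sample_id, names_to = "analyte",
                        values_to = "concentration") |>
    dplyr::left_join(dplyr::select(nt, analyte, parent = group),
                     by = "analyte") |>
    dplyr::group_by(sample_id, parent) |>
    dplyr::summarise(concentration = sum(concentration), .groups = "drop")
}

risk_sum <- function(profile, par_s, column) {
  profile |>
    dplyr::left_join(par_s, by = "parent") |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(value = sum(concentration / .data[[column]]),
                     .groups = "drop")
}

#' Hazard index and cancer risk per sample
#'
#' Screening-level risk characterization of the parent-summed PAH profile:
#' `HI = sum_i C_i / SL_nc_i` (unitless; 1 at the acceptability bound) and
#' `CR = sum_i C_i / SL_ca_i` expressed in cases per million (1 equals
#' one-in-a-million risk, since each `sl_ca` is defined at 1e-6 risk). Both
#' are exactly linear in the concentration vector.
#'
#' @param chemistry Wide chemistry tibble.
#' @param params Screening-level table, default [default_tox_params()].
#' @param scenario Scenarios to evaluate (default both).
#' @param lineage Analyte lineage for [aggregate_alkylated()].
#' @param on_missing What to do when a parent lacks screening levels:
#'   `"warn"` (skip with a warning, default) or `"error"`.
#' @return A tibble `sample_id`, `scenario`, `HI`, `CR`.
#' @export
risk_assess <- function(chemistry, params = default_tox_params(),
                        scenario = c("recreational_sediment",
                                     "residential_soil"),
                        lineage = default_analytes(),
                        on_missing = c("warn", "error")) {
  on_missing <- match.arg(on_missing)
  scenario <- match.arg(scenario, several.ok = TRUE)
  profile <- aggregate_alkylated(chemistry, lineage)
  purrr::map_dfr(scenario, function(sc) {
    par_s <- params[params$scenario == sc, ]
    missing <- setdiff(unique(profile$parent), par_s$parent)
    prof <- profile
    if (length(missing)) {
      msg <- paste("no", sc, "screening levels for:",
                   paste(missing, collapse = ", "))
      if (on_missing == "error") abort(msg) else warn(paste(msg, "- skipped"))
      prof <- prof[!prof$parent %in% missing, ]
    }
    hi <- risk_sum(prof, par_s, "sl_nc")
    cr <- risk_sum(prof, par_s, "sl_ca")
    tibble::tibble(sample_id = hi$sample_id, scenario = sc,
                   HI = hi$value, CR = cr$value)
  })
}
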