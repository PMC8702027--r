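#' Default study regions
#'
#' Three sampling regions emulating an urbanized estuary screening campaign:
#' an industrialized ship channel (`HSC`), an intermediate lakes area (`MCL`),
#' and an open bay (`GB`). `latent_offset` is the planted mean shift of the
#' latent contamination field in each region (log10 units), giving the
#' HSC > MCL > GB contamination gradient the generator emulates.
#'
#' @return A tibble with one row per region: `region`, `center_lon`,
#'   `center_lat`, `spread_km`, `sample_share`, `latent_offset`.
#' @export
default_regions <- function() {
  tibble::tribble(
    ~region, ~center_lon, ~center_lat, ~spread_km, ~sample_share, ~latent_offset,
    "HSC",   -95.25,       29.73,       8,          15 / 46,       2.0,
    "MCL",   -95.04,       29.56,       5,          10 / 46,       1.0,
    "GB",    -94.85,       29.43,      15,          21 / 46,       0.0
  )
}

#' Default analyte panel
#'
#' Forty analytes: the 16 EPA priority parent PAHs, 21 alkylated homologs
#' (each tied to a parent by `parent` and a typical abundance `fraction`
#' relative to that parent), and 3 exact totals. `base_log10` is the
#' geometric-mean baseline concentration (log10 ng/g dry weight) used by the
#' synthetic generator.
#'
#' @return A tibble with columns `analyte`, `parent` (`NA` for parents and
#'   totals), `is_total`, `fraction`, `base_log10`.
#' @export
default_analytes <- function() {
  parents <- tibble::tribble(
    ~analyte,                 ~base_log10,
    "naphthalene",            2.7,
    "acenaphthylene",         1.9,
    "acenaphthene",           2.0,
    "fluorene",               2.1,
    "phenanthrene",           2.6,
    "anthracene",             2.1,
    "fluoranthene",           2.7,
    "pyrene",                 2.65,
    "benz_a_anthracene",      2.3,
    "chrysene",               2.4,
    "benzo_b_fluoranthene",   2.35,
    "benzo_k_fluoranthene",   2.1,
    "benzo_a_pyrene",         2.3,
    "indeno_123cd_pyrene",    2.0,
    "dibenz_ah_anthracene",   1.7,
    "benzo_ghi_perylene",     2.0
  ) |>
    dplyr::mutate(parent = NA_character_, is_total = FALSE, fraction = NA_real_)

  alk <- function(parent, degrees, fracs) {
    tibble::tibble(
      analyte = paste0("C", degrees, "_", parent),
      parent = parent, is_total = FALSE, fraction = fracs,
      base_log10 = NA_real_
    )
  }
  homologs <- dplyr::bind_rows(
    alk("naphthalene", 1:4, c(0.8, 0.9, 0.6, 0.35)),
    alk("fluorene", 1:3, c(0.8, 0.9, 0.6)),
    alk("phenanthrene", 1:4, c(0.8, 0.9, 0.6, 0.35)),
    alk("anthracene", 1:2, c(0.8, 0.9)),
    alk("pyrene", 1:4, c(0.8, 0.9, 0.6, 0.35)),
    alk("chrysene", 1:4, c(0.8, 0.9, 0.6, 0.35))
  )
  # homolog baseline = parent baseline + log10(fraction)
  homologs$base_log10 <- parents$base_log10[match(homologs$parent, parents$analyte)] +
    log10(homologs$fraction)

  totals <- tibble::tibble(
    analyte = c("total_parent_pah16", "total_alkylated_pah", "total_pah"),
    parent = NA_character_, is_total = TRUE, fraction = NA_real_,
    base_log10 = NA_real_
  )
  dplyr::bind_rows(parents, homologs, totals) |>
    dplyr::select(analyte, parent, is_total, fraction, base_log10)
}

#' Default bioactivity endpoint panel
#'
#' Thirty-four concentration-response endpoints across five cell types
#' (iPSC-derived hepatocytes, neurons, cardiomyocytes, endothelial cells and
#' primary HUVECs). Each endpoint is one of three planted kinds:
#' \describe{
#'   \item{`chem`}{potency driven by the sample's aggregate PAH burden
#'     (`chem_weight` > 0); baseline potency `e0` (log10 dilution at zero
#'     burden) varies across endpoints.}
#'   \item{`nonpah`}{potency driven by a latent non-PAH contaminant score
#'     (`nonpah_weight` > 0) that is not part of the measured chemistry
#'     (its coupling to the contamination field is set by `nonpah_rho`).}
#'   \item{`null`}{no concentration-response signal; plates contain pure
#'     replicate noise.}
#' }
#' `direction` is the direction the response moves relative to vehicle and
#' `amp` the asymptotic effect amplitude in vehicle-scaled units.
#'
#' @return A tibble with columns `endpoint_id`, `cell_type`, `direction`,
#'   `driver`, `chem_weight`, `nonpah_weight`, `e0`, `amp`.
#' @export
default_endpoints <- function() {
  ep <- function(cell, stems, driver, direction, amp) {
    tibble::tibble(
      endpoint_id = paste0(cell, "_", stems), cell_type = cell,
      direction = direction, driver = driver, amp = amp
    )
  }
  out <- dplyr::bind_rows(
    ep("hepatocyte", c("cell_mean_area", "mito_intensity", "viability"),
       "chem", c("decrease", "decrease", "decrease"), c(0.7, 0.6, 0.8)),
    ep("hepatocyte", c("lipid_accum", "nuclei_count"),
       "nonpah", c("increase", "decrease"), c(0.5, 0.6)),
    ep("hepatocyte", c("albumin", "urea"),
       "null", c("decrease", "decrease"), c(0, 0)),
    ep("neuron", c("neurite_length", "branch_points"),
       "chem", c("decrease", "decrease"), c(0.6, 0.6)),
    ep("neuron", c("firing_rate", "burst_duration", "synchrony"),
       "nonpah", c("decrease", "increase", "decrease"), c(0.6, 0.5, 0.6)),
    ep("neuron", c("soma_size", "viability"),
       "null", c("decrease", "decrease"), c(0, 0)),
    ep("cardiomyocyte",
       c("beat_rate", "decay_to_rise", "peak_amplitude", "beat_irregularity",
         "calcium_transient", "viability"),
       "chem",
       c("decrease", "increase", "decrease", "increase", "decrease", "decrease"),
       c(0.7, 0.6, 0.6, 0.5, 0.7, 0.8)),
    ep("cardiomyocyte", "conduction", "null", "decrease", 0),
    ep("endothelial", "tube_length", "chem", "decrease", 0.7),
    ep("endothelial", c("tube_area", "branch_nodes"),
       "nonpah", c("decrease", "decrease"), c(0.6, 0.5)),
    ep("endothelial", c("migration", "permeability", "viability"),
       "null", c("decrease", "increase", "decrease"), c(0, 0, 0)),
    ep("HUVEC", c("tube_length", "tube_area", "branch_nodes"),
       "nonpah", c("decrease", "decrease", "decrease"), c(0.6, 0.5, 0.6)),
    ep("HUVEC", c("migration", "permeability", "viability", "mito_intensity"),
       "null", c("decrease", "increase", "decrease", "decrease"), c(0, 0, 0, 0))
  )
  out$chem_weight <- ifelse(out$driver == "chem", 1, 0)
  out$nonpah_weight <- ifelse(out$driver == "nonpah", 0.5, 0)
  # baseline potency (log10 dilution at zero burden): chem endpoints spread
  # so curve potencies differ; nonpah endpoints uniformly potent
  out$e0 <- NA_real_
  out$e0[out$driver == "chem"] <-
    seq(0.9, 1.3, length.out = sum(out$driver == "chem"))
  out$e0[out$driver == "nonpah"] <- -1.3
  dplyr::select(out, endpoint_id, cell_type, direction, driver,
                chem_weight, nonpah_weight, e0, amp)
}

#' Define a synthetic screening study design
#'
#' Bundles all parameters of the synthetic study generator: the sampling
#' regions, endpoint and analyte panels, the dilution ladder, replicate and
#' vehicle-well counts, the spatial autocorrelation of the latent
#' contamination field and the magnitudes of the planted signals.
#'
#' @param n_samples Number of sediment samples (default 46).
#' @param regions Region table, see [default_regions()].
#' @param endpoints Endpoint table, see [default_endpoints()].
#' @param analytes Analyte table, see [default_analytes()].
#' @param dilution_ladder Ordered extract dilutions, strictly decreasing from
#'   1.0 (default eight 3-fold steps).
#' @param n_replicates Replicate wells per dilution (default 3).
#' @param vehicle_wells Vehicle-control wells per endpoint (default 12).
#' @param noise_sd Replicate noise standard deviation in vehicle-scaled
#'   response units (default 0.05); also the half-width of the vehicle band
#'   used to define the true POD.
#' @param vehicle_mean Mean vehicle response; responses are generated already
#'   vehicle-relative, so this defaults to 1.
#' @param spatial_range_km Autocorrelation length (km) of the exponential
#'   covariance of the latent contamination field (default 20).
#' @param latent_loading Loading of each parent PAH log10-concentration on
#'   the latent field (default 0.10).
#' @param chem_noise_sd Independent log10 noise of each parent PAH
#'   concentration (default 0.65).
#' @param alk_jitter_sd Lognormal jitter (log10 sd) of alkylated homologs
#'   around their fixed fraction of the parent (default 0.1).
#' @param potency_slope Decrease in log10 EC50 per unit chemical burden for
#'   chemistry-driven endpoints (default 5).
#' @param potency_noise_sd Endpoint-by-sample log10 EC50 noise (default 0.15).
#' @param nonpah_slope Multiplier on the latent non-PAH score's contribution
#'   to log10 EC50 (per unit `nonpah_weight`, default 1).
#' @param nonpah_rho Correlation between the latent non-PAH contaminant
#'   score and the (standardized) latent PAH contamination field (default
#'   0.6), reflecting co-occurring contamination sources; set to 0 for a
#'   fully independent non-PAH driver.
#' @param hill Hill slope of the generated logistic curves (default 1.5).
#' @param seed Default seed carried with the design (default 1).
#'
#' @return An object of class `study_design` (a validated list).
#' @export
study_design <- function(n_samples = 46,
                         regions = default_regions(),
                         endpoints = default_endpoints(),
                         analytes = default_analytes(),
                         dilution_ladder = 3^-(0:7),
                         n_replicates = 3,
                         vehicle_wells = 12,
                         noise_sd = 0.05,
                         vehicle_mean = 1.0,
                         spatial_range_km = 20,
                         latent_loading = 0.10,
                         chem_noise_sd = 0.65,
                         alk_jitter_sd = 0.1,
                         potency_slope = 5,
                         potency_noise_sd = 0.15,
                         nonpah_slope = 1,
                         nonpah_rho = 0.6,
                         hill = 1.5,
                         seed = 1L) {
  design <- structure(
    list(
      n_samples = n_samples, regions = regions, endpoints = endpoints,
      analytes = analytes, dilution_ladder = dilution_ladder,
      n_replicates = n_replicates, vehicle_wells = vehicle_wells,
      noise_sd = noise_sd, vehicle_mean = vehicle_mean,
      spatial_range_km = spatial_range_km, latent_loading = latent_loading,
      chem_noise_sd = chem_noise_sd, alk_jitter_sd = alk_jitter_sd,
      potency_slope = potency_slope, potency_noise_sd = potency_noise_sd,
      nonpah_slope = nonpah_slope, nonpah_rho = nonpah_rho, hill = hill,
      seed = seed
    ),
    class = "study_design"
  )
  validate_design(design)
  design
}

validate_design <- function(d) {
  assert_that(is_count(d$n_samples) && d$n_samples >= 3,
              "n_samples must be an integer >= 3")
  assert_that(abs(sum(d$regions$sample_share) - 1) < 1e-8,
              "region sample_share values must sum to 1")
  assert_that(all(d$regions$sample_share > 0),
              "region sample_share values must be positive")
  assert_that(all(d$regions$spread_km >= 0), "spread_km must be >= 0")
  lad <- d$dilution_ladder
  assert_that(length(lad) >= 2 && abs(lad[1] - 1) < 1e-12 &&
                all(diff(lad) < 0) && all(lad > 0),
              "dilution_ladder must be strictly decreasing from 1.0 with positive entries")
  assert_that(is_count(d$n_replicates) && d$n_replicates >= 1,
              "n_replicates must be a positive integer")
  assert_that(is_count(d$vehicle_wells) && d$vehicle_wells >= 2,
              "vehicle_wells must be an integer >= 2")
  assert_that(is.numeric(d$noise_sd) && d$noise_sd > 0,
              "noise_sd must be > 0")
  assert_that(is.numeric(d$spatial_range_km) && d$spatial_range_km > 0,
              "spatial_range_km must be > 0")
  an <- d$analytes
  assert_that(all(c("analyte", "parent", "is_total") %in% names(an)),
              "analytes table must have analyte, parent, is_total columns")
  parents <- an$analyte[!an$is_total & is.na(an$parent)]
  bad <- an$parent[!is.na(an$parent)][!an$parent[!is.na(an$parent)] %in% parents]
  assert_that(length(bad) == 0,
              paste("alkylated homologs reference unknown parents:",
                    paste(unique(bad), collapse = ", ")))
  ep <- d$endpoints
  assert_that(all(ep$direction %in% c("increase", "decrease")),
              "endpoint direction must be 'increase' or 'decrease'")
  assert_that(all(ep$chem_weight >= 0) && all(ep$nonpah_weight >= 0),
              "endpoint weights must be nonnegative")
  invisible(d)
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>\n")
  cat("  samples:   ", x$n_samples, " in ", nrow(x$regions), " regions (",
      paste(x$regions$region, collapse = ", "), ")\n", sep = "")
  cat("  endpoints: ", nrow(x$endpoints), " across ",
      length(unique(x$endpoints$cell_type)), " cell types\n", sep = "")
  cat("  analytes:  ", nrow(x$analytes), " (",
      sum(!x$analytes$is_total & is.na(x$analytes$parent)), " parents, ",
      sum(!is.na(x$analytes$parent)), " alkylated, ",
      sum(x$analytes$is_total), " totals)\n", sep = "")
  cat("  dilutions: ", length(x$dilution_ladder), " points, max ",
      max(x$dilution_ladder), ", min ",
      signif(min(x$dilution_ladder), 3), "\n", sep = "")
  invisible(x)
}
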