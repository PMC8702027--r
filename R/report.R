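#' Per-region summary of overall ToxPi scores
#'
#' @param profiles A [toxpi_profiles()] result.
#' @param sites Site table with `sample_id` and `region`.
#' @return A tibble per region: `n`, `mean`, `median`, `q25`, `q75`, `min`,
#'   `max` of the overall score.
#' @export
region_summary <- function(profiles, sites) {
  assert_that("region" %in% names(sites), "sites must carry region labels")
  dplyr::left_join(
    dplyr::select(profiles, sample_id, overall),
    dplyr::select(sites, sample_id, region),
    by = "sample_id"
  ) |>
    dplyr::group_by(region) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(overall), median = median(overall),
      q25 = unname(quantile(overall, 0.25)),
      q75 = unname(quantile(overall, 0.75)),
      min = min(overall), max = max(overall), .groups = "drop"
    )
}

pipeline_files <- c(
  sites = "sites.csv", chemistry = "chemistry.csv", plates = "plates.csv",
  ground_truth = "ground_truth.csv", pods = "pods.csv", toxpi = "toxpi.csv",
  cluster_order = "cluster_order.json", mantel = "mantel.csv",
  krige_total_pah = "krige_total_pah.csv",
  krige_toxpi = "krige_toxpi_overall.csv", risk = "risk.csv",
  remediation = "remediation.csv",
  remediation_dumbbell = "remediation_dumbbell.csv",
  crosspred_chem2bio = "crosspred_chem2bio.csv",
  crosspred_bio2chem = "crosspred_bio2chem.csv",
  crosspred_summary = "crosspred_summary.csv",
  region_summary = "region_summary.csv"
)

#' Run the full screening analysis end to end
#'
#' Simulates a study (or uses one supplied), fits PODs, integrates ToxPi
#' scores, runs the Mantel screens, kriging maps, cross-predictions, risk
#' characterization and remediation comparison, and writes every stage's
#' table to `out_dir` along with a manifest of checksums. Deterministic for
#' a given seed and configuration.
#'
#' @param out_dir Output directory.
#' @param design A [study_design()].
#' @param seed Master seed.
#' @param study Optional pre-simulated `sed_study` (overrides design/seed).
#' @param n_perm Mantel permutations (default 10000).
#' @param n_grid Kriging grid resolution per axis (default 100).
#' @param scenario Risk scenario used for the remediation comparison
#'   (default recreational sediment contact).
#' @return Invisibly, a list with every stage's in-memory result and the
#'   output paths.
#' @export
run_pipeline <- function(out_dir, design = study_design(), seed = design$seed,
                         study = NULL, n_perm = 10000, n_grid = 100,
                         scenario = "recreational_sediment") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(key) file.path(out_dir, pipeline_files[[key]])

  if (is.null(study)) study <- simulate_study(design, seed)
  write_study(study, out_dir)

  pods <- fit_pods(study$plates)
  readr::write_csv(pods, path("pods"))

  scores <- scale_pods(pods)
  profiles <- toxpi_profiles(scores, cell_types = design$endpoints)
  readr::write_csv(profiles, path("toxpi"))
  slice_mat <- as.matrix(profiles[, attr(profiles, "slice_cols")])
  rownames(slice_mat) <- profiles$sample_id
  ord <- cluster_order(slice_mat)
  jsonlite::write_json(
    list(samples = profiles$sample_id[ord$row_order],
         endpoints = sub("^slice_", "",
                         attr(profiles, "slice_cols")[ord$col_order])),
    path("cluster_order"), pretty = TRUE
  )

  # spatial association screens: log10 concentrations and log10 PODs
  chem_feat <- dplyr::bind_cols(
    tibble::tibble(sample_id = study$chemistry$sample_id),
    tibble::as_tibble(chem_feature_matrix(study$chemistry))
  )
  bio_feat <- dplyr::bind_cols(
    tibble::tibble(sample_id = study$sites$sample_id),
    tibble::as_tibble(bio_feature_matrix(pods))
  )
  mantel <- dplyr::bind_rows(
    dplyr::mutate(mantel_screen(study$sites, chem_feat, n_perm = n_perm,
                                seed = seed + 11L), set = "chemistry"),
    dplyr::mutate(mantel_screen(study$sites, bio_feat, n_perm = n_perm,
                                seed = seed + 12L), set = "bioactivity")
  )
  readr::write_csv(mantel, path("mantel"))

  kr_chem <- krige(study$sites, study$chemistry$total_pah, n_grid = n_grid,
                   log_transform = TRUE)
  readr::write_csv(kr_chem$grid, path("krige_total_pah"))
  kr_bio <- krige(study$sites, profiles$overall, n_grid = n_grid,
                  log_transform = FALSE)
  readr::write_csv(kr_bio$grid, path("krige_toxpi"))

  risk <- risk_assess(study$chemistry)
  readr::write_csv(risk, path("risk"))

  rem <- remediation_table(dplyr::filter(risk, .data$scenario == !!scenario),
                           pods)
  readr::write_csv(rem, path("remediation"))
  readr::write_csv(remediation_dumbbell(rem), path("remediation_dumbbell"))

  cp <- cross_predict(study$chemistry, pods)
  readr::write_csv(cp$chem2bio$features, path("crosspred_chem2bio"))
  readr::write_csv(cp$bio2chem$features, path("crosspred_bio2chem"))
  cp_summary <- tibble::tibble(
    direction = c("chem2bio", "bio2chem"),
    lambda = c(cp$chem2bio$lambda, cp$bio2chem$lambda),
    mspe = c(cp$chem2bio$mspe, cp$bio2chem$mspe),
    n_significant = c(sum(cp$chem2bio$features$p_adj < 0.05, na.rm = TRUE),
                      sum(cp$bio2chem$features$p_adj < 0.05, na.rm = TRUE))
  )
  readr::write_csv(cp_summary, path("crosspred_summary"))

  regions <- region_summary(profiles, study$sites)
  readr::write_csv(regions, path("region_summary"))

  files <- file.path(out_dir, unname(pipeline_files))
  manifest <- list(
    package = "sedscreen",
    version = as.character(utils::packageVersion("sedscreen")),
    seed = seed,
    n_samples = design$n_samples,
    n_perm = n_perm,
    n_grid = n_grid,
    scenario = scenario,
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = lapply(setNames(files, names(pipeline_files)), function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    study = study, pods = pods, profiles = profiles, cluster_order = ord,
    mantel = mantel, krige_total_pah = kr_chem, krige_toxpi = kr_bio,
    risk = risk, remediation = rem, crosspred = cp,
    region_summary = regions, dir = out_dir
  ))
}

#' Read back the tables written by a pipeline run
#'
#' Errors with the name of the missing stage when an expected output is
#' absent.
#'
#' @param dir A directory written by [run_pipeline()].
#' @return A named list of tibbles (CSV stages only).
#' @export
read_pipeline_outputs <- function(dir) {
  csvs <- pipeline_files[grepl("\\.csv$", pipeline_files)]
  purrr::imap(csvs, function(f, stage) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      abort(sprintf("missing output for stage '%s': %s not found", stage, f))
    }
    readr::read_csv(p, show_col_types = FALSE)
  })
}
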