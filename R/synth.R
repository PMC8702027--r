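#' Generate synthetic sampling sites
#'
#' Draws site coordinates around each region's center with the region's
#' stated spread, allocating samples to regions by largest-remainder
#' apportionment of the design's `sample_share` values.
#'
#' @param design A [study_design()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble with columns `sample_id`, `lon`, `lat`, `region`.
#' @export
generate_sites <- function(design, seed = design$seed) {
  validate_design(design)
  reg <- design$regions
  n <- design$n_samples
  raw <- reg$sample_share * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  assert_that(all(counts >= 1), "every region must receive at least one sample")
  with_seed(seed, {
    out <- purrr::pmap_dfr(
      list(reg$region, reg$center_lon, reg$center_lat, reg$spread_km, counts),
      function(label, clon, clat, spread, k) {
        # convert a km spread to degrees: 1 deg lat ~ 110.574 km,
        # 1 deg lon ~ 111.320 * cos(lat) km
        lat <- clat + rnorm(k, 0, spread / 110.574)
        lon <- clon + rnorm(k, 0, spread / (111.320 * cos(clat * pi / 180)))
        tibble::tibble(
          sample_id = sprintf("%s-%02d", label, seq_len(k)),
          lon = lon, lat = lat, region = label
        )
      }
    )
    out
  })
}

# exact draw from a zero-mean Gaussian field with exponential covariance
# exp(-d / range_km) at the given sites (direct Cholesky; n is small)
sample_latent_field <- function(dist_km, range_km) {
  sigma <- exp(-dist_km / range_km)
  diag(sigma) <- diag(sigma) + 1e-8
  L <- chol(sigma)
  drop(crossprod(L, rnorm(nrow(sigma))))
}

#' Generate synthetic sediment chemistry
#'
#' Simulates a spatially autocorrelated latent contamination field
#' (exponential covariance, range `spatial_range_km`, plus the planted
#' per-region mean offsets), then parent PAH log10-concentrations as affine
#' functions of the field with independent noise, alkylated homologs as fixed
#' fractions of their parents with lognormal jitter, and totals as exact sums
#' of their constituents. Also draws the latent non-PAH contamination score
#' driving the non-PAH bioactivity endpoints (unit variance, correlated
#' `nonpah_rho` with the standardized field).
#'
#' @param sites Output of [generate_sites()].
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return A list with `chemistry` (wide tibble, one column per analyte,
#'   ng/g dry weight) and `truth` (tibble `sample_id`, `latent`, `nonpah`).
#' @export
generate_chemistry <- function(sites, design, seed = design$seed) {
  validate_design(design)
  an <- design$analytes
  n <- nrow(sites)
  with_seed(seed, {
    d_km <- geo_distances(sites)
    field <- sample_latent_field(d_km, design$spatial_range_km)
    offs <- design$regions$latent_offset[match(sites$region, design$regions$region)]
    latent <- offs + field
    # latent non-PAH contaminant score: unit-variance, correlated nonpah_rho
    # with the standardized contamination field (co-occurring sources)
    rho <- design$nonpah_rho %||% 0
    v <- rnorm(n)
    lat_std <- if (sd(latent) > 0) (latent - mean(latent)) / sd(latent) else 0
    nonpah <- rho * lat_std + sqrt(1 - rho^2) * v

    parents <- an[!an$is_total & is.na(an$parent), ]
    conc <- matrix(NA_real_, n, nrow(an), dimnames = list(NULL, an$analyte))
    for (k in seq_len(nrow(parents))) {
      lg <- parents$base_log10[k] + design$latent_loading * latent +
        rnorm(n, 0, design$chem_noise_sd)
      conc[, parents$analyte[k]] <- 10^lg
    }
    homologs <- an[!is.na(an$parent), ]
    for (k in seq_len(nrow(homologs))) {
      jitter <- 10^rnorm(n, 0, design$alk_jitter_sd)
      conc[, homologs$analyte[k]] <-
        homologs$fraction[k] * conc[, homologs$parent[k]] * jitter
    }
    conc[, "total_parent_pah16"] <- rowSums(conc[, parents$analyte, drop = FALSE])
    conc[, "total_alkylated_pah"] <- rowSums(conc[, homologs$analyte, drop = FALSE])
    conc[, "total_pah"] <- conc[, "total_parent_pah16"] + conc[, "total_alkylated_pah"]

    list(
      chemistry = dplyr::bind_cols(tibble::tibble(sample_id = sites$sample_id),
                                   tibble::as_tibble(conc)),
      truth = tibble::tibble(sample_id = sites$sample_id,
                             latent = latent, nonpah = nonpah)
    )
  })
}

# per-sample aggregate chemical burden for each endpoint:
# burden_j = sum_k w_jk * log10(1 + C_k / C_ref_k), always positive so that
# scaling the weights up always increases the burden. W is endpoints x
# non-total analytes; returns samples x endpoints.
chem_burden <- function(chemistry, analytes, W) {
  nt <- analytes[!analytes$is_total, ]
  conc <- as.matrix(chemistry[, nt$analyte, drop = FALSE])
  z <- sweep(log10(conc), 2, nt$base_log10, "-")
  softplus10(z) %*% t(W[, nt$analyte, drop = FALSE])
}

# endpoint weight vectors over non-total analytes: an explicit `chem_weights`
# list-column wins; otherwise chem_weight is spread equally across parent
# lineages (parent + its homologs share one lineage weight), so lineages
# with many measured homologs do not dominate the burden
endpoint_weight_matrix <- function(design) {
  nt <- design$analytes[!design$analytes$is_total, ]
  ep <- design$endpoints
  W <- matrix(0, nrow(ep), nrow(nt),
              dimnames = list(ep$endpoint_id, nt$analyte))
  if ("chem_weights" %in% names(ep)) {
    for (j in seq_len(nrow(ep))) {
      w <- ep$chem_weights[[j]]
      if (!is.null(w)) W[j, names(w)] <- w
    }
  } else {
    lineage <- ifelse(is.na(nt$parent), nt$analyte, nt$parent)
    n_lin <- length(unique(lineage))
    w_k <- 1 / (n_lin * table(lineage)[lineage])
    W <- outer(ep$chem_weight, as.numeric(w_k))
    dimnames(W) <- list(ep$endpoint_id, nt$analyte)
  }
  W
}

#' Generate synthetic concentration-response plate data
#'
#' For every sample x endpoint pair, simulates replicate responses along the
#' dilution ladder from a logistic-in-log-dilution curve whose EC50 (in
#' dilution units) decreases with the endpoint's weighted chemical burden
#' (and, for non-PAH endpoints, with the latent non-PAH score). Vehicle wells
#' are drawn around `vehicle_mean`. The true POD is recorded analytically as
#' the dilution where the noiseless curve crosses
#' `vehicle_mean` +/- 1 x `noise_sd`; pairs whose curve never crosses within
#' the tested range (and all endpoints with zero planted signal) are recorded
#' as inactive (`true_pod = Inf`).
#'
#' @param chem Chemistry tibble from [generate_chemistry()].
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @param nonpah Optional per-sample latent non-PAH scores (the `nonpah`
#'   column of the chemistry ground truth); zeros if omitted.
#' @return A list with `plates` (long tibble: `sample_id`, `endpoint_id`,
#'   `cell_type`, `dilution`, `replicate`, `response`; vehicle wells use
#'   `sample_id = "VEHICLE"` and `dilution = NA`) and `truth` (tibble
#'   `sample_id`, `endpoint_id`, `true_pod`, `true_log10_ec50`).
#' @export
generate_bioactivity <- function(chem, design, seed = design$seed,
                                 nonpah = NULL) {
  validate_design(design)
  ep <- design$endpoints
  n <- nrow(chem)
  if (is.null(nonpah)) nonpah <- rep(0, n)
  assert_that(length(nonpah) == n, "nonpah must have one value per sample")

  W <- endpoint_weight_matrix(design)
  burden <- chem_burden(chem, design$analytes, W)  # n x n_endpoints

  with_seed(seed, {
    lad <- design$dilution_ladder
    nd <- length(lad)
    nr <- design$n_replicates
    s <- design$noise_sd
    h <- design$hill

    eta <- matrix(rnorm(n * nrow(ep), 0, design$potency_noise_sd), n, nrow(ep))
    log10_ec50 <- matrix(rep(ep$e0, each = n), n, nrow(ep)) -
      design$potency_slope * burden -
      design$nonpah_slope * outer(nonpah, ep$nonpah_weight) + eta
    active_signal <- matrix(rep(ep$amp > 0, each = n), n, nrow(ep))
    log10_ec50[!active_signal] <- NA_real_

    # analytic band crossing of the noiseless curve:
    # amp / (1 + (ec50/x)^h) = s  =>  x = ec50 / (amp/s - 1)^(1/h)
    amp_m <- matrix(rep(ep$amp, each = n), n, nrow(ep))
    true_pod <- 10^log10_ec50 / (amp_m / s - 1)^(1 / h)
    true_pod[!active_signal | amp_m <= s] <- Inf
    true_pod[true_pod > max(lad)] <- Inf

    dir_m <- matrix(rep(ifelse(ep$direction == "increase", 1, -1), each = n),
                    n, nrow(ep))

    # long-format treated wells, layout fixed for determinism:
    # endpoint-major, then sample, dilution, replicate
    grid <- tidyr::expand_grid(
      endpoint = seq_len(nrow(ep)), sample = seq_len(n),
      dilution = lad, replicate = seq_len(nr)
    )
    ec <- 10^log10_ec50[cbind(grid$sample, grid$endpoint)]
    amp_v <- amp_m[cbind(grid$sample, grid$endpoint)]
    dir_v <- dir_m[cbind(grid$sample, grid$endpoint)]
    mu <- ifelse(is.na(ec), design$vehicle_mean,
                 design$vehicle_mean + dir_v * amp_v / (1 + (ec / grid$dilution)^h))
    plates <- tibble::tibble(
      sample_id = chem$sample_id[grid$sample],
      endpoint_id = ep$endpoint_id[grid$endpoint],
      cell_type = ep$cell_type[grid$endpoint],
      dilution = grid$dilution,
      replicate = grid$replicate,
      response = mu + rnorm(nrow(grid), 0, s)
    )
    vehicle <- tidyr::expand_grid(
      endpoint = seq_len(nrow(ep)), replicate = seq_len(design$vehicle_wells)
    )
    vehicle <- tibble::tibble(
      sample_id = "VEHICLE",
      endpoint_id = ep$endpoint_id[vehicle$endpoint],
      cell_type = ep$cell_type[vehicle$endpoint],
      dilution = NA_real_,
      replicate = vehicle$replicate,
      response = rnorm(nrow(vehicle), design$vehicle_mean, s)
    )
    truth <- tibble::tibble(
      sample_id = rep(chem$sample_id, times = nrow(ep)),
      endpoint_id = rep(ep$endpoint_id, each = n),
      true_pod = as.vector(true_pod),
      true_log10_ec50 = as.vector(log10_ec50)
    )
    list(plates = dplyr::bind_rows(plates, vehicle), truth = truth)
  })
}

#' Simulate a complete synthetic screening study
#'
#' Runs the three generators in sequence with seeds derived from one master
#' seed and returns all tables plus the planted ground truth.
#'
#' @param design A [study_design()].
#' @param seed Master integer seed (default the design's seed).
#' @return An object of class `sed_study`: a list with `sites`, `chemistry`,
#'   `plates`, `truth_field` (latent contamination and non-PAH scores) and
#'   `truth_pods`.
#' @export
simulate_study <- function(design = study_design(), seed = design$seed) {
  seed <- as.integer(seed)
  sites <- generate_sites(design, seed = seed)
  chem <- generate_chemistry(sites, design, seed = seed + 1000003L)
  bio <- generate_bioactivity(chem$chemistry, design, seed = seed + 2000003L,
                              nonpah = chem$truth$nonpah)
  structure(
    list(design = design, seed = seed, sites = sites,
         chemistry = chem$chemistry, plates = bio$plates,
         truth_field = chem$truth, truth_pods = bio$truth),
    class = "sed_study"
  )
}

#' @export
print.sed_study <- function(x, ...) {
  cat("<sed_study> seed", x$seed, "\n")
  cat(" ", nrow(x$sites), "sites;", ncol(x$chemistry) - 1, "analytes;",
      length(unique(x$plates$endpoint_id)), "endpoints;",
      nrow(x$plates), "wells\n")
  invisible(x)
}

#' Write a simulated study to CSV files
#'
#' Writes `sites.csv`, `chemistry.csv`, `plates.csv` and `ground_truth.csv`
#' (true PODs joined with the per-sample latent scores; inactive pairs carry
#' `true_pod = Inf`).
#'
#' @param study A `sed_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("sites.csv", "chemistry.csv", "plates.csv",
                            "ground_truth.csv"))
  readr::write_csv(study$sites, paths[1])
  readr::write_csv(study$chemistry, paths[2])
  readr::write_csv(study$plates, paths[3])
  gt <- dplyr::left_join(study$truth_pods, study$truth_field, by = "sample_id")
  readr::write_csv(gt, paths[4])
  invisible(paths)
}
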