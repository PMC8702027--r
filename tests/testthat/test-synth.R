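test_that("generators are deterministic given seed and design", {
  d <- small_design()
  s1 <- generate_sites(d, seed = 7)
  s2 <- generate_sites(d, seed = 7)
  expect_identical(s1, s2)
  c1 <- generate_chemistry(s1, d, seed = 7)
  c2 <- generate_chemistry(s1, d, seed = 7)
  expect_identical(c1, c2)
  b1 <- generate_bioactivity(c1$chemistry, d, seed = 7, nonpah = c1$truth$nonpah)
  b2 <- generate_bioactivity(c1$chemistry, d, seed = 7, nonpah = c1$truth$nonpah)
  expect_identical(b1, b2)
  expect_false(identical(generate_sites(d, seed = 8), s1))
})

test_that("site generation respects counts, labels and degenerate spread", {
  d <- study_design()
  sites <- generate_sites(d, seed = 1)
  expect_equal(nrow(sites), 46)
  expect_setequal(unique(sites$region), c("HSC", "MCL", "GB"))
  expect_false(anyDuplicated(sites$sample_id) > 0)

  d0 <- study_design(regions = dplyr::mutate(default_regions(), spread_km = 0))
  s0 <- generate_sites(d0, seed = 1)
  dmat <- geo_distances(s0)
  for (r in unique(s0$region)) {
    idx <- which(s0$region == r)
    expect_equal(max(dmat[idx, idx]), 0)
  }
})

test_that("total analytes are exact sums of their constituents", {
  d <- small_design()
  ch <- generate_chemistry(generate_sites(d, 3), d, 3)$chemistry
  an <- d$analytes
  parents <- an$analyte[!an$is_total & is.na(an$parent)]
  homologs <- an$analyte[!is.na(an$parent)]
  expect_equal(ch$total_parent_pah16,
               rowSums(ch[parents]), tolerance = 1e-9)
  expect_equal(ch$total_alkylated_pah,
               rowSums(ch[homologs]), tolerance = 1e-9)
  expect_equal(ch$total_pah, rowSums(ch[c(parents, homologs)]),
               tolerance = 1e-9)
})

test_that("latent field reproduces the planted exponential covariance", {
  # fixed sites, many field replicates; binned empirical correlation of the
  # field must match exp(-d/range) within Monte-Carlo error
  d <- study_design(spatial_range_km = 20)
  sites <- generate_sites(small_design(), seed = 5)
  dm <- geo_distances(sites)
  n <- nrow(sites)
  reps <- withr::with_seed(42, {
    vapply(1:200, function(i) sedscreen:::sample_latent_field(dm, 20),
           numeric(n))
  })
  emp_cov <- tcrossprod(reps - rowMeans(reps)) / (ncol(reps) - 1)
  ut <- upper.tri(dm)
  bins <- cut(dm[ut], breaks = c(0, 5, 10, 20, 40, Inf))
  emp <- tapply(emp_cov[ut], bins, mean)
  theo <- tapply(exp(-dm[ut] / 20), bins, mean)
  ok <- !is.na(emp)
  expect_true(all(abs(emp[ok] - theo[ok]) < 0.15))
  # variance close to 1
  expect_equal(mean(diag(emp_cov)), 1, tolerance = 0.2)
})

test_that("planted-null endpoints are inactive for every sample", {
  d <- small_design()
  st <- simulate_study(d, seed = 2)
  nulls <- d$endpoints$endpoint_id[d$endpoints$driver == "null"]
  tp <- st$truth_pods[st$truth_pods$endpoint_id %in% nulls, ]
  expect_true(all(!is.finite(tp$true_pod)))
})

test_that("recorded true POD equals the closed-form band crossing and a grid search", {
  d <- small_design(noise_sd = 0.05)
  st <- simulate_study(d, seed = 11)
  tp <- dplyr::inner_join(
    st$truth_pods,
    dplyr::select(d$endpoints, endpoint_id, amp, direction),
    by = "endpoint_id"
  )
  act <- tp[is.finite(tp$true_pod), ][1:20, ]
  # closed form: amp / (1 + (ec50/x)^h) = noise_sd
  closed <- 10^act$true_log10_ec50 / (act$amp / 0.05 - 1)^(1 / d$hill)
  expect_equal(act$true_pod, closed, tolerance = 1e-12)
  # dense-grid brute force at step 1e-4 in log10 dilution
  lg <- seq(-6, 0, by = 1e-4)
  for (i in 1:5) {
    resp <- gen_curve(10^lg, 10^act$true_log10_ec50[i], act$amp[i], d$hill,
                      act$direction[i])
    cross <- lg[which(abs(resp - 1) > 0.05)[1]]
    expect_lt(abs(cross - log10(act$true_pod[i])), 2e-4)
  }
})

test_that("doubling chemical weights never increases an active true POD", {
  d <- small_design()
  st1 <- simulate_study(d, seed = 9)
  d2 <- d
  d2$endpoints$chem_weight <- d$endpoints$chem_weight * 2
  st2 <- simulate_study(d2, seed = 9)
  j <- dplyr::inner_join(st1$truth_pods, st2$truth_pods,
                         by = c("sample_id", "endpoint_id"),
                         suffix = c("_1", "_2"))
  j <- dplyr::left_join(j, d$endpoints[c("endpoint_id", "chem_weight")],
                        by = "endpoint_id")
  chem_active <- j[j$chem_weight > 0 & is.finite(j$true_pod_1), ]
  expect_true(all(chem_active$true_pod_2 < chem_active$true_pod_1))
  other <- j[j$chem_weight == 0, ]
  expect_equal(other$true_pod_2, other$true_pod_1)
})

test_that("latent contamination is recoverable in ToxPi scores across simulations", {
  # synth invariant (positive rank correlation in >= 95% of runs) and the
  # sharper integration property (Spearman > 0.5 in >= 90%), plus the
  # planted region effect, over 100 simulated studies at default settings
  d <- study_design()
  rho <- numeric(100)
  hsc_gt_gb <- logical(100)
  for (s in 1:100) {
    st <- simulate_study(d, seed = 3000 + s)
    prof <- toxpi_profiles(scale_pods(truth_pods_tbl(st)), d$endpoints)
    lat <- st$truth_field$latent[match(prof$sample_id,
                                       st$truth_field$sample_id)]
    rho[s] <- cor(prof$overall, lat, method = "spearman")
    rs <- region_summary(prof, st$sites)
    hsc_gt_gb[s] <- rs$mean[rs$region == "HSC"] > rs$mean[rs$region == "GB"]
  }
  expect_gte(mean(rho > 0), 0.95)
  expect_gte(mean(rho > 0.5), 0.90)
  expect_gte(mean(hsc_gt_gb), 0.95)
})

test_that("written study CSVs round-trip", {
  d <- small_design()
  st <- simulate_study(d, seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  sites <- readr::read_csv(file.path(dir, "sites.csv"), show_col_types = FALSE)
  expect_equal(nrow(sites), d$n_samples)
  plates <- readr::read_csv(file.path(dir, "plates.csv"), show_col_types = FALSE)
  expect_true("VEHICLE" %in% plates$sample_id)
})
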