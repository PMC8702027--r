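#' Empirical semivariogram by the method of moments
#'
#' Bins site pairs by separation distance into lags of width `lag_size` and
#' averages the squared half-differences in each bin.
#'
#' @param d_km Symmetric distance matrix (km).
#' @param z Values at the sites (already transformed if applicable).
#' @param lag_size Lag width in km.
#' @param n_lags Number of lags.
#' @return A tibble `h` (mean pair distance), `gamma`, `n_pairs` per
#'   non-empty lag.
#' @export
empirical_variogram <- function(d_km, z, lag_size, n_lags = 15) {
  assert_that(lag_size > 0, "lag_size must be positive")
  ut <- upper.tri(d_km)
  h <- d_km[ut]
  g <- 0.5 * outer(z, z, "-")[ut]^2
  bin <- ceiling(h / lag_size)
  keep <- bin >= 1 & bin <= n_lags
  out <- tibble::tibble(bin = bin[keep], h = h[keep], gamma = g[keep]) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(h = mean(h), gamma = mean(gamma),
                     n_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::select(h, gamma, n_pairs)
  out
}

# spherical semivariogram model; gamma(0) = 0
spherical_gamma <- function(h, nugget, psill, range) {
  g <- ifelse(h >= range, nugget + psill,
              nugget + psill * (1.5 * h / range - 0.5 * (h / range)^3))
  g[h == 0] <- 0
  g
}

#' Fit a spherical semivariogram by weighted least squares
#'
#' Minimizes `sum N_j / h_j^2 * (gamma_j - model(h_j))^2` over nugget,
#' partial sill and range (all constrained nonnegative, range positive).
#'
#' @param emp Empirical semivariogram from [empirical_variogram()].
#' @return A list `nugget`, `psill`, `range`, `converged`.
#' @export
fit_spherical_variogram <- function(emp) {
  assert_that(nrow(emp) >= 3, "need at least 3 non-empty lags")
  w <- emp$n_pairs / emp$h^2
  obj <- function(p) {
    sum(w * (emp$gamma - spherical_gamma(emp$h, p[1], p[2], p[3]))^2)
  }
  init <- c(nugget = 0, psill = max(emp$gamma), range = max(emp$h) * 0.7)
  fit <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(0, 1e-12, max(emp$h) * 1e-3),
                      upper = c(Inf, Inf, max(emp$h) * 10))
  list(nugget = unname(fit$par[1]), psill = unname(fit$par[2]),
       range = unname(fit$par[3]), converged = fit$convergence == 0)
}

#' Ordinary kriging on a lon/lat grid
#'
#' Interpolates site values by ordinary kriging with a spherical
#' semivariogram. Values are log10-transformed first by default (mirroring
#' the mapping workflow for concentration-like quantities); the semivariogram
#' is estimated by the method of moments at the stated lag size and fitted by
#' weighted least squares, and the ordinary-kriging system (covariance form,
#' unbiasedness constraint) is solved for every prediction node. Duplicate
#' site coordinates are averaged with a warning so the system stays
#' nonsingular.
#'
#' @param sites Tibble `sample_id`, `lon`, `lat`.
#' @param values Numeric values at the sites (positive when
#'   `log_transform = TRUE`).
#' @param grid Optional tibble of prediction points (`lon`, `lat`). Default:
#'   a regular `n_grid` x `n_grid` grid over the site bounding box plus a 5%
#'   margin.
#' @param n_grid Grid resolution per axis (default 100).
#' @param margin Fractional bounding-box margin (default 0.05).
#' @param lag_size Semivariogram lag width in km. The default is the mean
#'   nearest-neighbor distance between sites (the conventional
#'   nearest-neighbor lag rule; a lag chosen in degrees, e.g. 0.003, is
#'   multiplied by ~111.2 km/degree to land on this scale).
#' @param n_lags Number of lags (default 15).
#' @param log_transform Log10-transform values before kriging (default TRUE);
#'   predictions are returned on the transformed scale in `pred` and
#'   back-transformed in `pred_raw`.
#' @param variogram Optional list `nugget`, `psill`, `range` to bypass
#'   fitting.
#' @return An object of class `sed_krige`: list with `grid` (tibble `lon`,
#'   `lat`, `pred`, `pred_raw`, `var`, `weight_sum`), `variogram`,
#'   `empirical`, `sites`, `z` and `log_transform`.
#' @export
krige <- function(sites, values, grid = NULL, n_grid = 100, margin = 0.05,
                  lag_size = NULL, n_lags = 15, log_transform = TRUE,
                  variogram = NULL) {
  assert_that(nrow(sites) >= 5, "kriging needs at least 5 sites")
  assert_that(length(values) == nrow(sites),
              "one value per site required")
  sites <- dplyr::mutate(sites, .value = values)
  key <- paste(sites$lon, sites$lat)
  if (anyDuplicated(key)) {
    warn("duplicate site coordinates: averaging values at co-located sites")
    sites <- sites |>
      dplyr::group_by(lon, lat) |>
      dplyr::summarise(sample_id = dplyr::first(sample_id),
                       .value = mean(.data$.value), .groups = "drop")
  }
  v <- sites$.value
  if (log_transform) {
    assert_that(all(v > 0), "log transform requires positive values")
    z <- log10(v)
  } else {
    z <- v
  }
  d <- geo_distances(sites)
  if (is.null(lag_size)) {
    nn <- apply(d + diag(Inf, nrow(d)), 1, min)
    lag_size <- mean(nn)
  }
  emp <- empirical_variogram(d, z, lag_size = lag_size, n_lags = n_lags)
  if (is.null(variogram)) {
    variogram <- if (stats::var(z) == 0) {
      list(nugget = 0, psill = 1e-12, range = max(max(d), lag_size),
           converged = TRUE)
    } else {
      fit_spherical_variogram(emp)
    }
  }
  sill <- variogram$nugget + variogram$psill
  cov_fun <- function(h) sill - spherical_gamma(h, variogram$nugget,
                                                variogram$psill,
                                                variogram$range)
  n <- nrow(sites)
  A <- rbind(cbind(cov_fun(d), 1), c(rep(1, n), 0))

  if (is.null(grid)) {
    rlon <- range(sites$lon); rlat <- range(sites$lat)
    mlon <- diff(rlon) * margin; mlat <- diff(rlat) * margin
    grid <- tidyr::expand_grid(
      lon = seq(rlon[1] - mlon, rlon[2] + mlon, length.out = n_grid),
      lat = seq(rlat[1] - mlat, rlat[2] + mlat, length.out = n_grid)
    )
  }
  d0 <- geosphere::distm(cbind(grid$lon, grid$lat),
                         cbind(sites$lon, sites$lat),
                         fun = geosphere::distHaversine) / 1000
  B <- rbind(t(cov_fun(d0)), 1)  # (n+1) x n_nodes
  W <- solve(A, B)
  pred <- drop(crossprod(W[seq_len(n), , drop = FALSE], z))
  kvar <- pmax(sill - colSums(B * W), 0)
  weight_sum <- colSums(W[seq_len(n), , drop = FALSE])

  structure(
    list(
      grid = dplyr::mutate(grid, pred = pred,
                           pred_raw = if (log_transform) 10^pred else pred,
                           var = kvar, weight_sum = weight_sum),
      variogram = variogram, empirical = emp,
      sites = sites[setdiff(names(sites), ".value")], z = z,
      lag_size = lag_size, log_transform = log_transform
    ),
    class = "sed_krige"
  )
}

#' @export
print.sed_krige <- function(x, ...) {
  cat(sprintf(
    "<sed_krige> %d nodes from %d sites; spherical(nugget %.3g, psill %.3g, range %.3g km)%s\n",
    nrow(x$grid), nrow(x$sites), x$variogram$nugget, x$variogram$psill,
    x$variogram$range, if (x$log_transform) "; log10 scale" else ""))
  invisible(x)
}
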