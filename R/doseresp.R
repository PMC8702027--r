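#' Vehicle-control statistics per endpoint
#'
#' Pools all vehicle wells (`sample_id == "VEHICLE"`) of each endpoint and
#' returns the control mean, standard deviation and well count that define
#' the vehicle band used for POD derivation.
#'
#' @param plates Long plate tibble (`sample_id`, `endpoint_id`, `dilution`,
#'   `replicate`, `response`).
#' @return A tibble `endpoint_id`, `mean`, `sd`, `n_wells`.
#' @export
vehicle_stats <- function(plates) {
  veh <- dplyr::filter(plates, sample_id == "VEHICLE")
  assert_that(nrow(veh) > 0, "no vehicle wells (sample_id == 'VEHICLE') found")
  out <- veh |>
    dplyr::group_by(endpoint_id) |>
    dplyr::summarise(mean = mean(response), sd = sd(response),
                     n_wells = dplyr::n(), .groups = "drop")
  assert_that(all(out$n_wells >= 2),
              "every endpoint needs at least 2 vehicle wells")
  out
}

#' Scale treated responses to the vehicle control
#'
#' Divides each treated response by its endpoint's vehicle mean, so the
#' vehicle band becomes `1 +/- sd/mean`. Vehicle wells are dropped from the
#' returned table.
#'
#' @param plates Long plate tibble including vehicle wells.
#' @param vstats Vehicle statistics, defaults to [vehicle_stats()] of
#'   `plates`.
#' @return The treated wells with `response` vehicle-scaled; the scaled
#'   vehicle band is attached as attribute `vehicle` (tibble `endpoint_id`,
#'   `mean_scaled = 1`, `sd_scaled`).
#' @export
scale_to_vehicle <- function(plates, vstats = vehicle_stats(plates)) {
  assert_that(all(abs(vstats$mean) > 0),
              "degenerate control: vehicle mean is zero for at least one endpoint")
  scaled <- plates |>
    dplyr::filter(sample_id != "VEHICLE") |>
    dplyr::left_join(dplyr::select(vstats, endpoint_id, v_mean = mean),
                     by = "endpoint_id") |>
    dplyr::mutate(response = response / v_mean) |>
    dplyr::select(-v_mean)
  attr(scaled, "vehicle") <- tibble::tibble(
    endpoint_id = vstats$endpoint_id,
    mean_scaled = 1,
    sd_scaled = vstats$sd / abs(vstats$mean)
  )
  scaled
}

logistic4 <- function(x, bottom, top, log10_ec50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10_ec50 - log10(x))))
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of
#' `f(x) = bottom + (top - bottom) / (1 + 10^(hill * (log10_ec50 - log10 x)))`
#' in log10 dilution, by Levenberg-Marquardt with five multi-start initial
#' EC50 values spread over the tested range. `bottom` is the low-dilution
#' asymptote when `hill > 0`; the sign of `hill` encodes the response
#' direction. Candidate fits are ranked by residual sum of squares, ties
#' broken by the smaller `|hill|`.
#'
#' @param series Data frame with columns `dilution` (positive fractions of
#'   extract stock) and `response` (vehicle-scaled), at least 4 distinct
#'   dilutions.
#' @return An object of class `logistic_fit`: a list with `bottom`, `top`,
#'   `log10_ec50`, `hill`, `converged`, `rss`, `n`.
#' @export
fit_logistic <- function(series) {
  x <- series$dilution
  y <- series$response
  assert_that(all(is.finite(x)) && all(x > 0), "dilutions must be positive")
  assert_that(length(unique(x)) >= 4, "need at least 4 distinct dilutions")
  assert_that(all(is.finite(y)), "responses must be finite")
  lx <- log10(x)

  if (diff(range(y)) == 0) {
    return(new_logistic_fit(y[1], y[1], mean(lx), 0, TRUE, 0, length(y)))
  }

  resid_fun <- function(p) {
    logistic4(x, p[1], p[2], p[3], p[4]) - y
  }
  b0 <- mean(y[lx == min(lx)])
  t0 <- mean(y[lx == max(lx)])
  h0 <- 1.5 * sign(stats::cor(lx, y))
  if (!is.finite(h0) || h0 == 0) h0 <- 1.5
  le_starts <- seq(min(lx), max(lx), length.out = 5)
  lower <- c(min(y) - 2 * diff(range(y)), min(y) - 2 * diff(range(y)),
             min(lx) - 2, -10)
  upper <- c(max(y) + 2 * diff(range(y)), max(y) + 2 * diff(range(y)),
             max(lx) + 2, 10)

  fits <- purrr::map(le_starts, function(le0) {
    start <- pmin(pmax(c(b0, t0, le0, h0), lower), upper)
    out <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fun, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(out)) return(NULL)
    list(par = out$par, rss = sum(out$fvec^2), info = out$info)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) {
    return(new_logistic_fit(mean(y), mean(y), mean(lx), 0, FALSE,
                            sum((y - mean(y))^2), length(y)))
  }
  rss <- purrr::map_dbl(fits, "rss")
  hills <- purrr::map_dbl(fits, ~ abs(.x$par[4]))
  best <- fits[[order(rss, hills)[1]]]
  new_logistic_fit(best$par[1], best$par[2], best$par[3], best$par[4],
                   best$info %in% 1:4, best$rss, length(y))
}

new_logistic_fit <- function(bottom, top, log10_ec50, hill, converged, rss, n) {
  structure(
    list(bottom = unname(bottom), top = unname(top),
         log10_ec50 = unname(log10_ec50), hill = unname(hill),
         converged = converged, rss = unname(rss), n = n),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> bottom %.3g, top %.3g, log10 EC50 %.3g, hill %.3g (%s, rss %.3g)\n",
    x$bottom, x$top, x$log10_ec50, x$hill,
    if (x$converged) "converged" else "NOT converged", x$rss))
  invisible(x)
}

#' @export
predict.logistic_fit <- function(object, dilution, ...) {
  logistic4(dilution, object$bottom, object$top, object$log10_ec50,
            object$hill)
}

# analytic inverse of the 4PL: dilution where f(x) = y, or NA when the
# level is outside the curve's open range
invert_logistic <- function(fit, y) {
  b <- fit$bottom; t <- fit$top; h <- fit$hill
  if (t == b || h == 0 || y == b) return(NA_real_)
  R <- (t - b) / (y - b) - 1
  if (!is.finite(R) || R <= 0) return(NA_real_)
  10^(fit$log10_ec50 - log10(R) / h)
}

#' Derive a point of departure from a fitted curve
#'
#' The POD is the smallest dilution in the tested range at which the fitted
#' curve departs from the vehicle band (control mean +/- one control SD),
#' obtained from the analytic logistic inverse (bisection fallback). A curve
#' already outside the band at the lowest tested dilution is clamped there
#' and flagged `extrapolated_low`; a curve that never exits the band within
#' the range (or a non-converged fit) is censored at the highest tested
#' dilution.
#'
#' @param fit A [fit_logistic()] result.
#' @param vehicle_mean,vehicle_sd Vehicle band center and half-width on the
#'   same (scaled) response scale as the fit.
#' @param tested_range Length-2 numeric, lowest and highest tested dilution.
#' @return A one-row tibble: `pod`, `censored`, `extrapolated_low`,
#'   `direction` (`"above"`, `"below"` or `"none"`), `quality`.
#' @export
derive_pod <- function(fit, vehicle_mean = 1, vehicle_sd, tested_range) {
  xmin <- min(tested_range); xmax <- max(tested_range)
  s <- vehicle_sd
  assert_that(s >= 0, "vehicle_sd must be nonnegative")
  out <- function(pod, censored, extrap, direction, quality = "ok") {
    tibble::tibble(pod = pod, censored = censored,
                   extrapolated_low = extrap, direction = direction,
                   quality = quality)
  }
  if (!isTRUE(fit$converged)) {
    return(out(xmax, TRUE, FALSE, "none", "nonconverged"))
  }
  if (fit$top == fit$bottom || fit$hill == 0) {
    return(out(xmax, TRUE, FALSE, "none"))
  }
  g_min <- predict(fit, xmin) - vehicle_mean
  if (abs(g_min) > s) {
    return(out(xmin, FALSE, TRUE, if (g_min > 0) "above" else "below"))
  }
  cand <- c(above = invert_logistic(fit, vehicle_mean + s),
            below = invert_logistic(fit, vehicle_mean - s))
  cand <- cand[is.finite(cand) & cand > xmin & cand <= xmax]
  if (length(cand) == 0) {
    g_max <- predict(fit, xmax) - vehicle_mean
    if (abs(g_max) > s) {
      # analytic inverse degenerate (e.g. band edge equals an asymptote):
      # bisect |f - mean| - s in log10 dilution to relative tolerance 1e-6
      f <- function(lx) abs(predict(fit, 10^lx) - vehicle_mean) - s
      root <- stats::uniroot(f, c(log10(xmin), log10(xmax)),
                             tol = 1e-6 * abs(log10(xmin)))$root
      pod <- 10^root
      return(out(pod, FALSE, FALSE,
                 if (predict(fit, xmax) > vehicle_mean) "above" else "below"))
    }
    return(out(xmax, TRUE, FALSE, "none"))
  }
  i <- which.min(cand)
  out(unname(cand[i]), FALSE, FALSE, names(cand)[i])
}

# F-test of the 4-parameter logistic against the constant (mean-only) model
curve_beats_flat <- function(y, fit, alpha) {
  n <- length(y)
  if (n <= 4) return(TRUE)
  rss0 <- sum((y - mean(y))^2)
  if (rss0 == 0) return(FALSE)
  if (fit$rss >= rss0) return(FALSE)
  f <- ((rss0 - fit$rss) / 3) / (fit$rss / (n - 4))
  stats::pf(f, 3, n - 4, lower.tail = FALSE) < alpha
}

#' Fit PODs for every sample x endpoint series in a plate table
#'
#' Full concentration-response stage: computes pooled vehicle statistics,
#' vehicle-scales the treated wells, fits a four-parameter logistic curve per
#' sample x endpoint and derives the POD by the vehicle-band crossing rule.
#'
#' Before a POD is derived, the logistic fit must beat a constant
#' (no-response) model in an F-test at level `flat_test_alpha`; series where
#' it does not are treated as showing no concentration response and censored.
#' This guards against calling activity on pure replicate noise, where an
#' unconstrained four-parameter curve can drift marginally outside the
#' vehicle band.
#'
#' @param plates Long plate tibble including vehicle wells (as written by
#'   [write_study()] to `plates.csv`).
#' @param flat_test_alpha Significance level of the curve-vs-constant F-test
#'   gate (default 0.05); `NULL` disables the gate.
#' @return A tibble with one row per sample x endpoint: `sample_id`,
#'   `endpoint_id`, `cell_type` (if present), `pod`, `censored`,
#'   `extrapolated_low`, `direction`, `quality`, fit diagnostics (`bottom`,
#'   `top`, `log10_ec50`, `hill`, `rss`, `converged`).
#' @export
fit_pods <- function(plates, flat_test_alpha = 0.05) {
  vstats <- vehicle_stats(plates)
  scaled <- scale_to_vehicle(plates, vstats)
  band <- attr(scaled, "vehicle")
  has_ct <- "cell_type" %in% names(scaled)

  keys <- dplyr::distinct(scaled, sample_id, endpoint_id,
                          dplyr::across(dplyr::any_of("cell_type")))
  groups <- split(scaled[, c("dilution", "response")],
                  paste(scaled$sample_id, scaled$endpoint_id, sep = "\r"))
  key_id <- paste(keys$sample_id, keys$endpoint_id, sep = "\r")

  res <- purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    ser <- groups[[key_id[i]]]
    fit <- fit_logistic(ser)
    sdj <- band$sd_scaled[band$endpoint_id == keys$endpoint_id[i]]
    if (!is.null(flat_test_alpha) && !curve_beats_flat(ser$response, fit,
                                                      flat_test_alpha)) {
      pod <- tibble::tibble(pod = max(ser$dilution), censored = TRUE,
                            extrapolated_low = FALSE, direction = "none",
                            quality = "no_response")
    } else {
      pod <- derive_pod(fit, vehicle_mean = 1, vehicle_sd = sdj,
                        tested_range = range(ser$dilution))
    }
    dplyr::bind_cols(
      keys[i, ], pod,
      tibble::tibble(bottom = fit$bottom, top = fit$top,
                     log10_ec50 = fit$log10_ec50, hill = fit$hill,
                     rss = fit$rss, converged = fit$converged)
    )
  })
  res
}
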