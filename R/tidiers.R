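#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn fit_logistic Tidy the fitted curve parameters.
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("bottom", "top", "log10_ec50", "hill"),
    estimate = c(x$bottom, x$top, x$log10_ec50, x$hill)
  )
}

#' @describeIn fit_logistic One-row fit summary.
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, converged = x$converged)
}

#' @describeIn mantel_test One-row tidy result.
#' @param x A `mantel_test`.
#' @param ... Unused.
#' @export
tidy.mantel_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_perm = x$n_perm, exhaustive = x$exhaustive, n = x$n)
}

#' @describeIn mantel_test Alias of `tidy()` for this single-statistic test.
#' @export
glance.mantel_test <- function(x, ...) tidy.mantel_test(x)

#' @describeIn loocv_ridge Per-feature prediction performance.
#' @param x A `crosspred`.
#' @param ... Unused.
#' @export
tidy.crosspred <- function(x, ...) x$features

#' @describeIn loocv_ridge One-row model summary.
#' @export
glance.crosspred <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, mspe = x$mspe, n = x$n,
    n_features = nrow(x$features),
    n_significant = sum(x$features$p_adj < 0.05, na.rm = TRUE),
    n_dropped = length(x$dropped)
  )
}

#' @describeIn krige The prediction grid as a tibble.
#' @param x A `sed_krige`.
#' @param ... Unused.
#' @export
tidy.sed_krige <- function(x, ...) x$grid

#' @describeIn krige One-row summary of the fitted semivariogram.
#' @export
glance.sed_krige <- function(x, ...) {
  tibble::tibble(
    nugget = x$variogram$nugget, psill = x$variogram$psill,
    range_km = x$variogram$range, lag_size_km = x$lag_size,
    n_sites = nrow(x$sites), n_nodes = nrow(x$grid),
    log_transform = x$log_transform
  )
}
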