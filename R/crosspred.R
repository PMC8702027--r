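#' Build a samples x features matrix from a tidy table
#'
#' @param df Tibble with a `sample_id` column and numeric feature columns.
#' @return A numeric matrix with sample ids as rownames.
#' @export
feature_matrix <- function(df) {
  cols <- setdiff(names(df), "sample_id")
  m <- as.matrix(df[cols])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  m
}

#' Bioactivity feature matrix from a POD table
#'
#' PODs on the log10 dilution scale; censored PODs enter at the maximum
#' tested dilution recorded for them.
#'
#' @param pods POD tibble from [fit_pods()].
#' @return samples x endpoints matrix of log10 PODs.
#' @export
bio_feature_matrix <- function(pods) {
  wide <- pods |>
    dplyr::mutate(value = log10(pod)) |>
    tidyr::pivot_wider(id_cols = sample_id, names_from = endpoint_id,
                       values_from = value)
  feature_matrix(wide)
}

#' Chemistry feature matrix from a concentration table
#'
#' Concentrations on the `log10(x + m/2)` scale, where `m` is the smallest
#' positive value of each analyte (a standard start shift tolerating zeros).
#'
#' @param chemistry Wide chemistry tibble (`sample_id` + analyte columns).
#' @return samples x analytes matrix.
#' @export
chem_feature_matrix <- function(chemistry) {
  m <- feature_matrix(chemistry)
  for (j in seq_len(ncol(m))) {
    pos <- m[, j][m[, j] > 0]
    shift <- if (length(pos)) min(pos) / 2 else 1
    m[, j] <- log10(m[, j] + shift)
  }
  m
}

#' Leave-one-out cross-validated multivariate ridge regression
#'
#' Predicts every column of `Y` from all columns of `X` with one shared
#' ridge penalty, evaluated by leave-one-out cross-validation: for each held
#' out sample, both matrices' columns are standardized with the training
#' fold's statistics, ridge coefficients are estimated on the training fold
#' only, and the held-out prediction is returned to the original scale by
#' multiplying by the training-fold standard deviation and adding the
#' training-fold mean. The penalty is chosen on a grid to minimize the
#' overall mean-squared prediction error.
#'
#' @param X,Y Numeric samples x features matrices with matching rows (and
#'   matching rownames when present).
#' @param lambda_grid Ridge penalty grid; default 30 log-spaced points on
#'   `[1e-3, 1e3] * ncol(X)`.
#' @return An object of class `crosspred`: `predicted` (cross-validated
#'   predictions at the chosen penalty, original scale), `lambda`,
#'   `lambda_grid`, `mspe_grid`, `mspe`, `features` (per-feature `r`,
#'   `p_value`, `p_adj`, `degenerate`), `dropped` (constant `Y` columns
#'   excluded), `n`.
#' @export
loocv_ridge <- function(X, Y, lambda_grid = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  assert_that(n == nrow(Y), "X and Y must have the same samples")
  if (!is.null(rownames(X)) && !is.null(rownames(Y))) {
    assert_that(identical(rownames(X), rownames(Y)),
                "X and Y sample ids must match")
  }
  assert_that(n >= 5, "insufficient data: need at least 5 samples")
  assert_that(!anyNA(X) && !anyNA(Y), "missing values are not supported")

  const_y <- apply(Y, 2, function(v) stats::var(v) == 0)
  dropped <- colnames(Y)[const_y]
  if (length(dropped)) {
    warn(paste("excluding constant response columns:",
               paste(dropped, collapse = ", ")))
    Y <- Y[, !const_y, drop = FALSE]
  }
  assert_that(ncol(Y) >= 1, "no non-constant response columns left")
  if (is.null(lambda_grid)) {
    lambda_grid <- 10^seq(-3, 3, length.out = 30) * ncol(X)
  }
  assert_that(all(lambda_grid > 0), "ridge penalties must be positive")

  q <- ncol(Y)
  nl <- length(lambda_grid)
  preds <- array(NA_real_, c(n, q, nl))
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; Ytr <- Y[-i, , drop = FALSE]
    mx <- colMeans(Xtr); sx <- apply(Xtr, 2, sd); sx[sx == 0] <- 1
    my <- colMeans(Ytr); sy <- apply(Ytr, 2, sd); sy[sy == 0] <- 1
    Xs <- sweep(sweep(Xtr, 2, mx), 2, sx, "/")
    Ys <- sweep(sweep(Ytr, 2, my), 2, sy, "/")
    sv <- svd(Xs)
    uty <- crossprod(sv$u, Ys)                      # r x q
    xh <- (X[i, ] - mx) / sx
    xv <- drop(xh %*% sv$v)                         # length r
    for (l in seq_len(nl)) {
      shrink <- sv$d / (sv$d^2 + lambda_grid[l])
      pred_s <- drop((xv * shrink) %*% uty)
      preds[i, , l] <- pred_s * sy + my
    }
  }
  mspe_grid <- vapply(seq_len(nl),
                      function(l) mean((preds[, , l] - Y)^2), numeric(1))
  best <- which.min(mspe_grid)
  predicted <- preds[, , best]
  dimnames(predicted) <- dimnames(Y)
  features <- prediction_significance(predicted, Y)
  structure(
    list(predicted = predicted, lambda = lambda_grid[best],
         lambda_grid = lambda_grid, mspe_grid = mspe_grid,
         mspe = mspe_grid[best], features = features,
         dropped = dropped, n = n),
    class = "crosspred"
  )
}

#' Per-feature significance of cross-validated predictions
#'
#' Pearson correlation between cross-validated predictions and observed
#' values for each feature, with two-sided p-values and Benjamini-Hochberg
#' adjustment across the features of this prediction direction. Features
#' with constant predictions (or constant observations) have no defined
#' correlation and are flagged `degenerate` and reported non-significant.
#'
#' @param predicted,actual Matching samples x features matrices.
#' @return A tibble `feature`, `r`, `p_value`, `p_adj`, `degenerate`.
#' @export
prediction_significance <- function(predicted, actual) {
  predicted <- as.matrix(predicted); actual <- as.matrix(actual)
  assert_that(all(dim(predicted) == dim(actual)),
              "predicted and actual must have matching shapes")
  nm <- colnames(actual) %||% paste0("f", seq_len(ncol(actual)))
  res <- purrr::map_dfr(seq_len(ncol(actual)), function(j) {
    p <- predicted[, j]; a <- actual[, j]
    if (sd(p) == 0 || sd(a) == 0) {
      return(tibble::tibble(feature = nm[j], r = NA_real_,
                            p_value = NA_real_, degenerate = TRUE))
    }
    ct <- stats::cor.test(p, a, method = "pearson")
    tibble::tibble(feature = nm[j], r = unname(ct$estimate),
                   p_value = ct$p.value, degenerate = FALSE)
  })
  res$p_adj <- NA_real_
  ok <- !res$degenerate
  res$p_adj[ok] <- bh_adjust(res$p_value[ok])
  dplyr::select(res, feature, r, p_value, p_adj, degenerate)
}

#' @export
print.crosspred <- function(x, ...) {
  nsig <- sum(x$features$p_adj < 0.05, na.rm = TRUE)
  cat(sprintf(
    "<crosspred> n = %d, %d features; lambda = %.4g, MSPE = %.4g; %d significant (p_adj < 0.05)\n",
    x$n, nrow(x$features), x$lambda, x$mspe, nsig))
  invisible(x)
}

#' Cross-predict bioactivity and chemistry in both directions
#'
#' Runs [loocv_ridge()] chemistry -> bioactivity and bioactivity ->
#' chemistry through one shared code path, using the standard transforms
#' ([chem_feature_matrix()], [bio_feature_matrix()]).
#'
#' @param chemistry Wide chemistry tibble.
#' @param pods POD tibble from [fit_pods()].
#' @param lambda_grid Optional shared penalty grid.
#' @return A named list with `crosspred` objects `chem2bio` and `bio2chem`.
#' @export
cross_predict <- function(chemistry, pods, lambda_grid = NULL) {
  Xc <- chem_feature_matrix(chemistry)
  Xb <- bio_feature_matrix(pods)
  assert_that(identical(rownames(Xc), rownames(Xb)),
              "chemistry and pods must cover the same samples in the same order")
  list(
    chem2bio = loocv_ridge(Xc, Xb, lambda_grid = lambda_grid),
    bio2chem = loocv_ridge(Xb, Xc, lambda_grid = lambda_grid)
  )
}
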