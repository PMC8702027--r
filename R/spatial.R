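#' Pairwise geographic distances between sites
#'
#' Haversine great-circle distances in km from WGS84 lon/lat coordinates.
#'
#' @param sites Tibble with `sample_id`, `lon`, `lat`.
#' @return A symmetric matrix (km) with `sample_id` dimnames.
#' @export
geo_distances <- function(sites) {
  assert_that(all(c("lon", "lat") %in% names(sites)),
              "sites must have lon and lat columns")
  assert_that(all(is.finite(sites$lon)) && all(is.finite(sites$lat)) &&
                all(abs(sites$lat) <= 90),
              "invalid coordinates")
  m <- geosphere::distm(cbind(sites$lon, sites$lat),
                        fun = geosphere::distHaversine) / 1000
  ids <- sites$sample_id %||% as.character(seq_len(nrow(sites)))
  dimnames(m) <- list(ids, ids)
  m
}

#' Pairwise feature dissimilarities between samples
#'
#' Single-feature mode: squared differences `(v_i - v_j)^2` of one numeric
#' feature. Global mode: `1 - q_ij` where `q_ij` is the Spearman correlation
#' of the two samples' full feature vectors (entries in [0, 2]).
#'
#' @param x A numeric vector (mode `"squared"`) or a samples x features
#'   numeric matrix (mode `"spearman"`).
#' @param mode `"squared"` or `"spearman"`.
#' @return A symmetric dissimilarity matrix with zero diagonal.
#' @export
feature_distances <- function(x, mode = c("squared", "spearman")) {
  mode <- match.arg(mode)
  if (mode == "squared") {
    x <- as.numeric(x)
    assert_that(length(x) >= 3, "need at least 3 samples")
    outer(x, x, function(a, b) (a - b)^2)
  } else {
    x <- as.matrix(x)
    assert_that(ncol(x) >= 2, "global mode needs at least 2 features")
    1 - stats::cor(t(x), method = "spearman")
  }
}

all_permutations <- function(n) {
  # Heap-free recursive enumeration; intended for small n (exhaustive Mantel)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Mantel permutation test of spatial association
#'
#' Correlates the upper triangles of a geographic distance matrix and a
#' feature dissimilarity matrix (Pearson), with significance from
#' simultaneous row/column permutations of the feature matrix. The test is
#' one-sided (greater): spatial association means nearby sites have similar
#' feature values. `p = (1 + #\{perm >= observed\}) / (n_perm + 1)`; in
#' exhaustive mode all `n!` relabelings are enumerated and
#' `p = #\{perm >= observed\} / n!` (the identity is included).
#'
#' @param d_geo,d_feat Symmetric distance/dissimilarity matrices with
#'   matching dimensions (and matching dimnames when present).
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Optional integer seed for the permutation draw.
#' @param exhaustive Enumerate all permutations (only sensible for n <= 8).
#' @return An object of class `mantel_test`: `statistic`, `p_value`,
#'   `n_perm`, `exhaustive`, `n`.
#' @export
mantel_test <- function(d_geo, d_feat, n_perm = 10000, seed = NULL,
                        exhaustive = FALSE) {
  d_geo <- as.matrix(d_geo); d_feat <- as.matrix(d_feat)
  n <- nrow(d_geo)
  assert_that(n >= 4, "Mantel test needs at least 4 samples")
  assert_that(all(dim(d_feat) == c(n, n)), "matrix dimensions must match")
  if (!is.null(rownames(d_geo)) && !is.null(rownames(d_feat))) {
    assert_that(identical(rownames(d_geo), rownames(d_feat)),
                "matrix sample ids must match")
  }
  ut <- upper.tri(d_geo)
  vg <- d_geo[ut]
  vf <- d_feat[ut]
  assert_that(stats::var(vg) > 0 && stats::var(vf) > 0,
              "undefined Mantel statistic: zero variance in a distance matrix")
  obs <- stats::cor(vg, vf)
  tol <- 1e-12

  if (exhaustive) {
    assert_that(n <= 8, "exhaustive enumeration limited to n <= 8")
    perms <- all_permutations(n)
    stats_all <- apply(perms, 1, function(p) {
      stats::cor(vg, d_feat[p, p][ut])
    })
    p_value <- mean(stats_all >= obs - tol)
    n_used <- nrow(perms)
  } else {
    stat_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        p <- sample.int(n)
        stats::cor(vg, d_feat[p, p][ut])
      }, numeric(1))
    })
    p_value <- (1 + sum(stat_perm >= obs - tol)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(
    list(statistic = obs, p_value = p_value, n_perm = n_used,
         exhaustive = exhaustive, n = n),
    class = "mantel_test"
  )
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("<mantel_test> r = %.4f, p = %.4g (%s, n = %d)\n",
              x$statistic, x$p_value,
              if (x$exhaustive) sprintf("all %d permutations", x$n_perm)
              else sprintf("%d permutations", x$n_perm),
              x$n))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  assert_that(all(is.na(p) | (p >= 0 & p <= 1)),
              "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Mantel screen of many features against site locations
#'
#' Runs a single-feature Mantel test (squared feature differences vs
#' geographic distance) for every numeric column of `features`, then applies
#' Benjamini-Hochberg correction across features. Constant features are
#' reported with `NA` statistics and excluded from the adjustment.
#'
#' @param sites Site table (for [geo_distances()]) or a precomputed
#'   geographic distance matrix.
#' @param features Tibble with `sample_id` plus numeric feature columns, in
#'   the same sample order as `sites`.
#' @param n_perm,seed Passed to [mantel_test()]; each feature uses its own
#'   seeded permutation stream derived from `seed`.
#' @return A tibble `feature`, `statistic`, `p_value`, `p_adj`, `n_perm`.
#' @export
mantel_screen <- function(sites, features, n_perm = 10000, seed = NULL) {
  d_geo <- if (is.matrix(sites)) sites else geo_distances(sites)
  cols <- setdiff(names(features), "sample_id")
  cols <- cols[vapply(features[cols], is.numeric, logical(1))]
  res <- purrr::map_dfr(seq_along(cols), function(i) {
    v <- features[[cols[i]]]
    if (stats::var(v) == 0) {
      return(tibble::tibble(feature = cols[i], statistic = NA_real_,
                            p_value = NA_real_, n_perm = n_perm))
    }
    mt <- mantel_test(d_geo, feature_distances(v, "squared"),
                      n_perm = n_perm,
                      seed = if (is.null(seed)) NULL else seed + i)
    tibble::tibble(feature = cols[i], statistic = mt$statistic,
                   p_value = mt$p_value, n_perm = n_perm)
  })
  res$p_adj <- NA_real_
  ok <- !is.na(res$p_value)
  res$p_adj[ok] <- bh_adjust(res$p_value[ok])
  res
}
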