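#' Inverse-scale PODs to ToxPi slice scores
#'
#' Converts PODs into [0, 1] slice scores, inversely scaled so that 0 marks
#' the lowest observed bioactivity (the highest POD among the samples) and 1
#' the highest observed bioactivity (the lowest POD). Scaling is per endpoint
#' on log10 PODs by default; both the pooled-dataset alternative and linear
#' POD scaling are available. Censored PODs (no observed bioactivity) score
#' 0, as does every sample of an endpoint with zero POD range.
#'
#' @param pods POD tibble from [fit_pods()] (needs `sample_id`,
#'   `endpoint_id`, `pod`, `censored`).
#' @param scale_on Scale PODs on `"log10"` (default) or `"linear"` values.
#' @param by Normalize per `"endpoint"` (default) or over the `"pooled"`
#'   dataset.
#' @return A tibble `sample_id`, `endpoint_id`, `score`.
#' @export
scale_pods <- function(pods, scale_on = c("log10", "linear"),
                       by = c("endpoint", "pooled")) {
  scale_on <- match.arg(scale_on)
  by <- match.arg(by)
  assert_that(all(c("sample_id", "endpoint_id", "pod", "censored") %in%
                    names(pods)),
              "pods must have sample_id, endpoint_id, pod, censored columns")
  tr <- if (scale_on == "log10") log10 else identity
  x <- pods |>
    dplyr::mutate(t_pod = ifelse(censored, NA_real_, tr(pod)))
  if (by == "pooled") {
    rng <- range(x$t_pod, na.rm = TRUE)
    x <- dplyr::mutate(x, lo = rng[1], hi = rng[2])
  } else {
    x <- x |>
      dplyr::group_by(endpoint_id) |>
      dplyr::mutate(
        lo = if (all(is.na(t_pod))) NA_real_ else min(t_pod, na.rm = TRUE),
        hi = if (all(is.na(t_pod))) NA_real_ else max(t_pod, na.rm = TRUE)
      ) |>
      dplyr::ungroup()
  }
  x |>
    dplyr::mutate(
      score = dplyr::case_when(
        censored | is.na(t_pod) ~ 0,
        hi == lo ~ 0,
        TRUE ~ (hi - t_pod) / (hi - lo)
      )
    ) |>
    dplyr::select(sample_id, endpoint_id, score)
}

#' Aggregate slice scores into ToxPi profiles
#'
#' Computes the overall ToxPi score of each sample as the weighted mean of
#' its slice scores (equal weights by default), per-cell-type scores as the
#' unweighted mean over each cell type's endpoints, and ranks samples by
#' overall score (rank 1 = most bioactive; ties broken by input order).
#'
#' @param scores Slice scores from [scale_pods()].
#' @param cell_types Optional tibble `endpoint_id`, `cell_type` (e.g. the
#'   design's endpoint table); per-cell-type scores are added when supplied.
#' @param weights Optional nonnegative slice weights, a named vector keyed by
#'   `endpoint_id`.
#' @return A `sed_toxpi` tibble: `sample_id`, one `slice_<endpoint>` column
#'   per endpoint, optional `ct_<cell type>` columns, `overall`, `rank`.
#' @export
toxpi_profiles <- function(scores, cell_types = NULL, weights = NULL) {
  eps <- sort(unique(scores$endpoint_id))
  if (is.null(weights)) {
    weights <- setNames(rep(1, length(eps)), eps)
  }
  assert_that(all(eps %in% names(weights)),
              "weights must cover every endpoint")
  assert_that(all(weights >= 0), "slice weights must be nonnegative")
  w <- weights[eps] / sum(weights[eps])

  wide <- scores |>
    dplyr::arrange(match(endpoint_id, eps)) |>
    tidyr::pivot_wider(id_cols = sample_id, names_from = endpoint_id,
                       values_from = score)
  slice_mat <- as.matrix(wide[, eps, drop = FALSE])
  overall <- drop(slice_mat %*% w)

  out <- tibble::tibble(sample_id = wide$sample_id)
  slice_tbl <- tibble::as_tibble(slice_mat)
  names(slice_tbl) <- paste0("slice_", eps)
  out <- dplyr::bind_cols(out, slice_tbl)

  ct_cols <- character(0)
  if (!is.null(cell_types)) {
    ct <- cell_types$cell_type[match(eps, cell_types$endpoint_id)]
    for (type in unique(ct[!is.na(ct)])) {
      nm <- paste0("ct_", type)
      out[[nm]] <- rowMeans(slice_mat[, which(ct == type), drop = FALSE])
      ct_cols <- c(ct_cols, nm)
    }
  }
  out$overall <- overall
  out$rank <- rank(-overall, ties.method = "first")
  structure(out, class = c("sed_toxpi", class(out)),
            slice_cols = paste0("slice_", eps), ct_cols = ct_cols)
}

#' Hierarchical-clustering leaf orders for a score matrix
#'
#' Average-linkage agglomerative clustering on Euclidean distances, applied
#' to rows and to columns, as used to organize bioactivity heatmaps.
#' Deterministic for a given input; a single row or column yields the
#' identity order.
#'
#' @param mat Numeric matrix (e.g. samples x endpoints slice scores).
#' @return A list with integer vectors `row_order` and `col_order`.
#' @export
cluster_order <- function(mat) {
  mat <- as.matrix(mat)
  ord <- function(m) {
    if (nrow(m) < 2) return(seq_len(nrow(m)))
    stats::hclust(stats::dist(m, method = "euclidean"),
                  method = "average")$order
  }
  list(row_order = ord(mat), col_order = ord(t(mat)))
}
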