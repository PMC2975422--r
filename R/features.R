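#' Map genes into the (AG, AD) feature space
#'
#' For each gene, computes the per-condition means of the log expression
#' values, the average expression level `ag = (mean_a + mean_b) / 2`, and
#' the average difference `ad = |mean_a - mean_b|`. On log-scale data `ad`
#' equals the absolute log fold change, so the feature space is the familiar
#' MA-plot geometry: a dense core of equally expressed genes near `ad = 0`
#' and a sparse boundary where differentially expressed genes concentrate.
#' Per-condition unbiased sample variances are carried along for the
#' t-statistic ranker (`NA` when a condition has a single sample).
#'
#' @param x a `deg_matrix` with a two-condition design, on the log scale.
#' @param rescale if `TRUE`, min-max rescale both axes to \[0, 1\] after
#'   computing them. Off by default: the neighbour radius of the pruning
#'   step is interpreted in raw log units, matching the convention that its
#'   search range runs from 0 to the maximum AD value.
#' @return a tibble of class `deg_features` with columns `gene_id`,
#'   `mean_a`, `mean_b`, `ag`, `ad`, `var_a`, `var_b`, one row per gene in
#'   matrix row order.
#' @export
#' @examples
#' sim <- simulate_deg_matrix(n_genes = 200, n_deg = 10, seed = 1)
#' compute_features(sim$matrix)
compute_features <- function(x, rescale = FALSE) {
  stopifnot(inherits(x, "deg_matrix"))
  if (!x$log_scale) {
    abort("matrix must be log-scale; apply `log_transform()` first.")
  }
  a <- samples_in(x, "A")
  b <- samples_in(x, "B")
  va <- x$values[, a, drop = FALSE]
  vb <- x$values[, b, drop = FALSE]
  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  out <- tibble(
    gene_id = x$gene_ids,
    mean_a = mean_a,
    mean_b = mean_b,
    ag = (mean_a + mean_b) / 2,
    ad = abs(mean_a - mean_b),
    var_a = row_var(va, mean_a),
    var_b = row_var(vb, mean_b)
  )
  if (rescale) {
    out$ag <- minmax01(out$ag)
    out$ad <- minmax01(out$ad)
  }
  structure(out,
            class = c("deg_features", class(out)),
            p_a = length(a), p_b = length(b), rescaled = rescale)
}

row_var <- function(v, mu) {
  p <- ncol(v)
  if (p < 2L) return(rep(NA_real_, nrow(v)))
  rowSums((v - mu)^2) / (p - 1)
}

minmax01 <- function(z) {
  rng <- range(z)
  if (rng[1L] == rng[2L]) return(rep(0, length(z)))
  (z - rng[1L]) / (rng[2L] - rng[1L])
}

as_features <- function(features) {
  if (!is.data.frame(features) || !all(c("ag", "ad") %in% names(features))) {
    abort("`features` must be a data frame with `ag` and `ad` columns, as from `compute_features()`.")
  }
  features
}
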