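#' Simulate a two-condition expression matrix with known true DEGs
#'
#' Generates log2-scale data reproducing the geometry that density-based
#' pruning exploits: a dense core of equally expressed genes near `ad = 0`
#' in the (AG, AD) plane, and a sparse boundary population of true DEGs
#' biased toward high expression and large between-condition difference.
#'
#' Non-DEG gene `i` draws a baseline `mu_i ~ N(baseline_mean, baseline_sd^2)`
#' and every sample value is `mu_i` plus `N(0, noise_sd^2)` replicate noise.
#' A true DEG draws its baseline with an additional `deg_level_shift`
#' (verified DEGs tend to be highly expressed) and its condition-B values
#' are offset by `delta_i = s_i * U(effect_min, effect_max)` with the sign
#' `s_i` equally likely up or down. A `hard_fraction` of the DEGs forgo the
#' expression-level shift, emulating the smaller portion of true DEGs that
#' sit mixed with non-DEGs at ordinary expression levels.
#'
#' @param n_genes total number of genes.
#' @param n_deg number of true DEGs (`0 <= n_deg <= n_genes`).
#' @param n_a,n_b samples per condition.
#' @param baseline_mean,baseline_sd log2-scale parameters of the non-DEG
#'   expression-level distribution.
#' @param noise_sd within-gene replicate noise, log2 units.
#' @param deg_level_shift additive bias raising DEG baseline expression,
#'   log2 units.
#' @param effect_min,effect_max bounds of the DEG shift magnitude, log2
#'   units.
#' @param hard_fraction fraction of DEGs generated without the expression
#'   level shift.
#' @param seed integer seed; the same seed yields a bit-identical dataset.
#' @return a list of class `deg_simulation` with elements `matrix` (a
#'   `deg_matrix` with design attached; condition labels "A"/"B") and
#'   `truth` (character vector of true DEG identifiers).
#' @export
#' @examples
#' sim <- simulate_deg_matrix(n_genes = 1000, n_deg = 20, seed = 42)
#' sim$matrix
#' head(sim$truth)
simulate_deg_matrix <- function(n_genes = 10000L, n_deg = 100L,
                                n_a = 10L, n_b = 10L,
                                baseline_mean = 7, baseline_sd = 1.5,
                                noise_sd = 0.3, deg_level_shift = 1.5,
                                effect_min = 1, effect_max = 3,
                                hard_fraction = 0.1, seed) {
  if (missing(seed)) abort("`seed` is required for a reproducible simulation.")
  if (n_genes < 1L) abort("`n_genes` must be positive.")
  if (n_deg < 0L || n_deg > n_genes) abort("`n_deg` must be in 0..n_genes.")
  if (n_a < 1L || n_b < 1L) abort("`n_a` and `n_b` must be positive.")
  if (baseline_sd <= 0 || noise_sd <= 0) abort("sd parameters must be positive.")
  if (effect_min > effect_max) abort("`effect_min` must not exceed `effect_max`.")
  if (hard_fraction < 0 || hard_fraction > 1) abort("`hard_fraction` must be in [0, 1].")

  p <- n_a + n_b
  gene_ids <- sprintf("g%0*d", max(5L, nchar(n_genes)), seq_len(n_genes))
  sample_ids <- c(sprintf("A%02d", seq_len(n_a)), sprintf("B%02d", seq_len(n_b)))

  sim <- withr::with_seed(seed, {
    deg_idx <- if (n_deg > 0L) sort(sample.int(n_genes, n_deg)) else integer()
    n_hard <- round(hard_fraction * n_deg)
    hard_idx <- if (n_hard > 0L) deg_idx[sample.int(n_deg, n_hard)] else integer()

    mu <- rnorm(n_genes, baseline_mean, baseline_sd)
    mu[deg_idx] <- mu[deg_idx] + deg_level_shift
    mu[hard_idx] <- mu[hard_idx] - deg_level_shift  # hard DEGs: no level shift

    values <- mu + matrix(rnorm(n_genes * p, 0, noise_sd), n_genes, p)
    if (n_deg > 0L) {
      sign <- sample(c(-1, 1), n_deg, replace = TRUE)
      delta <- sign * runif(n_deg, effect_min, effect_max)
      b_cols <- n_a + seq_len(n_b)
      values[deg_idx, b_cols] <- values[deg_idx, b_cols] + delta
    }
    list(values = values, deg_idx = deg_idx)
  })

  design <- group_design(stats::setNames(rep(c("A", "B"), c(n_a, n_b)), sample_ids))
  mat <- deg_matrix(sim$values, design = design, gene_ids = gene_ids,
                    sample_ids = sample_ids, log_scale = TRUE)
  structure(list(matrix = mat, truth = gene_ids[sim$deg_idx]),
            class = "deg_simulation")
}

#' @export
print.deg_simulation <- function(x, ...) {
  cat(sprintf("<deg_simulation> %d genes (%d true DEGs) x %d samples\n",
              nrow(x$matrix$values), length(x$truth), ncol(x$matrix$values)))
  invisible(x)
}
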