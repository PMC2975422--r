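#' Benchmark DEG rankers with and without density pruning
#'
#' Runs the full comparison protocol on one dataset: computes features,
#' prunes once with the given parameters, then ranks genes by each requested
#' statistic both without pruning and with survivors-first ("append")
#' pruning, and evaluates every ranking against the truth set (prefix ROC,
#' unnormalised partial AUC up to `k_max`, and true-positive counts at the
#' `ks` cutoffs).
#'
#' @param x a `deg_matrix` with a design.
#' @param truth character vector of true DEG identifiers present in `x`.
#' @param methods subset of `c("fc", "rp", "ttest", "wad")`. The t-statistic
#'   is skipped with a warning when either condition has fewer than two
#'   samples.
#' @param n0 density threshold for pruning.
#' @param r0,target_k pruning radius, or desired survivor count (exactly one).
#' @param k_max partial-AUC cutoff.
#' @param ks top-K grid for true-positive counts.
#' @param variance_floor passed to [score_ttest()].
#' @return a tibble of class `deg_benchmark`, one row per method x pruning
#'   state, with columns `method`, `pruned`, `partial_auc`, `top_<k>` for
#'   each cutoff, and a list column `evaluation` holding the full
#'   [evaluate_ranking()] objects. Attributes carry the `deg_pruning` used
#'   and the truth enrichment before/after pruning; see
#'   [glance.deg_benchmark()].
#' @export
#' @examples
#' sim <- simulate_deg_matrix(n_genes = 1000, n_deg = 20, n_a = 4, n_b = 4, seed = 7)
#' bm <- run_benchmark(sim$matrix, sim$truth, target_k = 200, k_max = 300,
#'                     ks = c(50, 100))
#' bm
#' glance(bm)
run_benchmark <- function(x, truth,
                          methods = c("fc", "rp", "ttest", "wad"),
                          n0 = 4, r0 = NULL, target_k = NULL,
                          k_max = 1000L, ks = c(150L, 250L, 350L, 450L, 550L),
                          variance_floor = 1e-8) {
  stopifnot(inherits(x, "deg_matrix"))
  methods <- match.arg(methods, c("fc", "rp", "ttest", "wad"), several.ok = TRUE)
  truth <- unique(as.character(truth))
  missing <- setdiff(truth, x$gene_ids)
  if (length(missing)) {
    abort(paste0("truth id(s) not in the matrix: ",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  p1 <- sum(x$design == "A")
  p2 <- sum(x$design == "B")
  if ("ttest" %in% methods && (p1 < 2L || p2 < 2L)) {
    warn(sprintf("skipping t-test: %d vs %d samples (need >= 2 per condition).",
                 p1, p2))
    methods <- setdiff(methods, "ttest")
  }
  if (!length(methods)) abort("no applicable ranking method remains.")
  ks <- as.integer(ks[ks <= nrow(x$values)])
  if (!length(ks)) ks <- nrow(x$values)

  features <- compute_features(x)
  pruning <- prune_genes(features, n0 = n0, r0 = r0, target_k = target_k)
  n_kept <- sum(pruning$kept)
  truth_kept <- sum(x$gene_ids[pruning$kept] %in% truth)

  rows <- list()
  evals <- list()
  for (m in methods) {
    for (pruned in c(FALSE, TRUE)) {
      rk <- rank_degs(x, method = m, features = features,
                      pruning = if (pruned) pruning else NULL,
                      mode = "append", variance_floor = variance_floor)
      ev <- evaluate_ranking(rk, truth, k_max = k_max, ks = ks)
      row <- tibble(method = m, pruned = pruned, partial_auc = ev$partial_auc)
      tk <- stats::setNames(as.list(ev$topk$n_true), paste0("top_", ev$topk$k))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(row, as_tibble(tk))
      evals[[length(evals) + 1L]] <- ev
    }
  }
  out <- dplyr::bind_rows(rows)
  out$evaluation <- evals
  structure(out,
            class = c("deg_benchmark", class(out)),
            pruning = pruning,
            n_genes = nrow(x$values),
            n_truth = length(truth),
            truth_kept = truth_kept,
            enrichment_before = enrichment_score(length(truth), nrow(x$values)),
            enrichment_after = if (n_kept > 0L) {
              enrichment_score(truth_kept, n_kept)
            } else NA_real_)
}

#' @export
print.deg_benchmark <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<deg_benchmark> %d genes, %d true DEGs; r0 = %g, n0 = %d\n",
              g$n_genes, g$n_truth, g$r0, g$n0))
  cat(sprintf("  enrichment %.4g -> %.4g (%.2gx)\n",
              g$enrichment_before, g$enrichment_after, g$fold_enrichment))
  NextMethod()
}

#' @rdname run_benchmark
#' @param ... unused.
#' @export
glance.deg_benchmark <- function(x, ...) {
  pr <- attr(x, "pruning")
  before <- attr(x, "enrichment_before")
  after <- attr(x, "enrichment_after")
  tibble(
    n_genes = attr(x, "n_genes"),
    n_truth = attr(x, "n_truth"),
    r0 = attr(pr, "r0"),
    n0 = attr(pr, "n0"),
    n_kept = sum(pr$kept),
    truth_kept = attr(x, "truth_kept"),
    enrichment_before = before,
    enrichment_after = after,
    fold_enrichment = after / before
  )
}

#' @rdname run_benchmark
#' @export
tidy.deg_benchmark <- function(x, ...) {
  out <- as_tibble(x)
  out$evaluation <- NULL
  out
}

#' Serialise a benchmark report to JSON
#'
#' Writes a versioned, diff-able JSON report (floats at 6 significant
#' digits) containing the pruning summary, enrichment, and per-method
#' partial AUCs and top-K counts.
#'
#' @param x a `deg_benchmark`.
#' @param path output path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
benchmark_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "deg_benchmark"))
  g <- glance(x)
  body <- tidy(x)
  report <- list(
    schema = "degprune-benchmark/1",
    summary = as.list(g),
    results = body
  )
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 6, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
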