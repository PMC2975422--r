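#' Fold-change score
#'
#' On log-scale data the absolute difference of condition means equals the
#' absolute log fold change, so fold change ranks genes directly by `ad`.
#' A score of 1 on log2 data corresponds to the conventional two-fold-change
#' significance cutoff.
#'
#' @param features a `deg_features` tibble.
#' @return numeric scores, one per gene (higher = more DEG-like).
#' @family DEG scores
#' @export
score_fold_change <- function(features) {
  features <- as_features(features)
  features$ad
}

#' Weighted average difference (WAD) score
#'
#' The absolute log fold change weighted by a min-max-normalised average
#' expression level: `w = (ag - min(ag)) / (max(ag) - min(ag))`,
#' `score = ad * w`. The weight upranks highly expressed genes, reflecting
#' the observation that experimentally verified DEGs tend to be highly
#' expressed. When all `ag` are equal the weight is 1 everywhere and WAD
#' degenerates to fold change.
#'
#' @inheritParams score_fold_change
#' @return numeric scores, one per gene.
#' @family DEG scores
#' @export
score_wad <- function(features) {
  features <- as_features(features)
  rng <- range(features$ag)
  w <- if (rng[1L] == rng[2L]) {
    rep(1, nrow(features))
  } else {
    (features$ag - rng[1L]) / (rng[2L] - rng[1L])
  }
  features$ad * w
}

#' Absolute t-statistic score
#'
#' The classical two-sample pooled-variance Student t statistic, in absolute
#' value. A small `variance_floor` is added to the squared standard error so
#' that zero-variance genes receive a finite (large) score instead of
#' dividing by zero — the classical t's tendency to be misled by genes with
#' tiny variances is precisely the bias that density pruning mitigates.
#' Set `welch = TRUE` for the unequal-variance (Welch) form.
#'
#' @param x a `deg_matrix` with at least two samples per condition.
#' @param variance_floor small positive constant added to the squared
#'   standard error.
#' @param welch use the Welch unequal-variance statistic instead of the
#'   pooled form.
#' @return numeric scores, one per gene.
#' @family DEG scores
#' @export
score_ttest <- function(x, variance_floor = 1e-8, welch = FALSE) {
  stopifnot(inherits(x, "deg_matrix"))
  a <- samples_in(x, "A")
  b <- samples_in(x, "B")
  p1 <- length(a)
  p2 <- length(b)
  if (p1 < 2L || p2 < 2L) {
    abort(paste0("the t-statistic needs at least 2 samples per condition ",
                 "(found ", p1, " and ", p2, "); ",
                 "use fold change or rank product for such designs."))
  }
  if (!is.numeric(variance_floor) || variance_floor <= 0) {
    abort("`variance_floor` must be a positive number.")
  }
  va <- x$values[, a, drop = FALSE]
  vb <- x$values[, b, drop = FALSE]
  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  s2a <- row_var(va, mean_a)
  s2b <- row_var(vb, mean_b)
  se2 <- if (welch) {
    s2a / p1 + s2b / p2
  } else {
    sp2 <- ((p1 - 1) * s2a + (p2 - 1) * s2b) / (p1 + p2 - 2)
    sp2 * (1 / p1 + 1 / p2)
  }
  abs(mean_a - mean_b) / sqrt(se2 + variance_floor)
}

#' Rank product score
#'
#' For each of the `P1 x P2` ordered condition-A/condition-B sample pairs,
#' genes are ranked by the pairwise log difference `value_B - value_A`,
#' once descending (rank 1 = most up-regulated) and once ascending (rank 1 =
#' most down-regulated), with average ranks on ties. `RP_up` and `RP_down`
#' are the geometric means of the respective ranks across all pairs
#' (accumulated in log space), and the score is
#' `-log(min(RP_up, RP_down))`, so extreme genes in either direction score
#' high. The permutation-based significance estimate of the original rank
#' product method is out of scope here; the statistic is used purely as a
#' ranking.
#'
#' @param x a `deg_matrix` with at least one sample per condition.
#' @return numeric scores, one per gene.
#' @family DEG scores
#' @export
score_rank_product <- function(x) {
  stopifnot(inherits(x, "deg_matrix"))
  a <- samples_in(x, "A")
  b <- samples_in(x, "B")
  n <- nrow(x$values)
  log_up <- numeric(n)
  log_down <- numeric(n)
  for (ai in a) {
    for (bi in b) {
      d <- x$values[, bi] - x$values[, ai]
      r_up <- rank(-d, ties.method = "average")
      log_up <- log_up + log(r_up)
      # with average ties the ascending rank is N + 1 - descending rank
      log_down <- log_down + log(n + 1 - r_up)
    }
  }
  np <- length(a) * length(b)
  -pmin(log_up, log_down) / np
}

#' Rank genes by score, optionally honouring a pruning
#'
#' Produces a total order over genes, highest score first, with ties broken
#' stably by input row order. When a [prune_genes()] result is supplied,
#' mode `"append"` (the default) places all surviving genes, sorted by
#' score, ahead of all pruned genes, also sorted by score — so a top-K
#' prefix is well defined even when K exceeds the survivor count and ROC
#' curves with and without pruning share the same axes. Mode `"exclude"`
#' drops pruned genes from the ranking altogether.
#'
#' @param scores numeric vector of finite per-gene scores (higher = more
#'   DEG-like).
#' @param gene_ids gene identifiers aligned with `scores`; defaults to the
#'   `gene_id` column of `pruning` when available.
#' @param pruning an optional `deg_pruning` aligned with `scores`.
#' @param mode `"append"` or `"exclude"`; see Details.
#' @param method optional label recorded on the result.
#' @return a tibble of class `deg_ranking` with columns `rank`, `gene_id`,
#'   `score`, `kept`.
#' @export
#' @examples
#' rank_genes(c(3, 1, 2), gene_ids = c("a", "b", "c"))
rank_genes <- function(scores, gene_ids = NULL, pruning = NULL,
                       mode = c("append", "exclude"), method = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    abort("`scores` must be a finite numeric vector.")
  }
  n <- length(scores)
  if (is.null(gene_ids) && !is.null(pruning)) gene_ids <- pruning$gene_id
  gene_ids <- gene_ids %||% paste0("gene_", seq_len(n))
  if (length(gene_ids) != n) abort("`gene_ids` must match `scores` in length.")
  kept <- rep(TRUE, n)
  if (!is.null(pruning)) {
    if (nrow(pruning) != n) abort("`pruning` must cover the same genes as `scores`.")
    kept <- pruning$kept
  }
  # stable sort: score descending, then input order
  ord <- order(-scores, seq_len(n))
  if (!is.null(pruning)) {
    if (mode == "exclude") {
      ord <- ord[kept[ord]]
    } else {
      ord <- c(ord[kept[ord]], ord[!kept[ord]])
    }
  }
  out <- tibble(
    rank = seq_along(ord),
    gene_id = gene_ids[ord],
    score = scores[ord],
    kept = kept[ord]
  )
  structure(out, class = c("deg_ranking", class(out)),
            method = method, mode = if (is.null(pruning)) "none" else mode,
            n_total = n)
}

#' One-call scoring and ranking of a matrix
#'
#' Convenience pipeline wrapper: computes features, applies the chosen
#' scoring statistic and returns the ranking, optionally after density
#' pruning.
#'
#' @param x a `deg_matrix` with a design.
#' @param method one of `"fc"`, `"rp"`, `"ttest"`, `"wad"`.
#' @param features optional precomputed `deg_features` (avoids recomputation).
#' @param pruning optional precomputed `deg_pruning`.
#' @param mode pruned-gene handling, see [rank_genes()].
#' @param variance_floor passed to [score_ttest()].
#' @param welch passed to [score_ttest()].
#' @return a `deg_ranking` tibble.
#' @export
rank_degs <- function(x, method = c("fc", "rp", "ttest", "wad"),
                      features = NULL, pruning = NULL,
                      mode = c("append", "exclude"),
                      variance_floor = 1e-8, welch = FALSE) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (is.null(features) && method %in% c("fc", "wad")) {
    features <- compute_features(x)
  }
  scores <- switch(method,
    fc = score_fold_change(features),
    wad = score_wad(features),
    ttest = score_ttest(x, variance_floor = variance_floor, welch = welch),
    rp = score_rank_product(x)
  )
  rank_genes(scores, gene_ids = x$gene_ids, pruning = pruning,
             mode = mode, method = method)
}

#' @export
print.deg_ranking <- function(x, ...) {
  cat(sprintf("<deg_ranking> %d genes, method = %s, pruning mode = %s\n",
              nrow(x), attr(x, "method") %||% "?", attr(x, "mode")))
  NextMethod()
}

#' @rdname rank_genes
#' @param x a `deg_ranking`.
#' @param ... unused.
#' @export
glance.deg_ranking <- function(x, ...) {
  tibble(
    method = attr(x, "method") %||% NA_character_,
    mode = attr(x, "mode"),
    n_ranked = nrow(x),
    n_total = attr(x, "n_total"),
    n_kept = sum(x$kept)
  )
}

#' @rdname rank_genes
#' @export
tidy.deg_ranking <- function(x, ...) {
  as_tibble(x)
}
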