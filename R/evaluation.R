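#' Enrichment score of true DEGs in a gene list
#'
#' The fraction of a gene list made up of true DEGs. The ratio of this score
#' after pruning to before pruning is the fold enrichment that density-based
#' pruning is designed to deliver.
#'
#' @param n_true_in_list number of true DEGs contained in the list.
#' @param list_size total number of genes in the list (`>= 1`).
#' @return the ratio `n_true_in_list / list_size`.
#' @export
enrichment_score <- function(n_true_in_list, list_size) {
  if (list_size < 1L) abort("`list_size` must be at least 1.")
  if (n_true_in_list < 0L || n_true_in_list > list_size) {
    abort("`n_true_in_list` must be between 0 and `list_size`.")
  }
  n_true_in_list / list_size
}

check_truth <- function(ranking, truth) {
  stopifnot(inherits(ranking, "deg_ranking"))
  truth <- unique(as.character(truth))
  if (length(truth) < 1L) abort("truth set must be non-empty.")
  missing <- setdiff(truth, ranking$gene_id)
  if (length(missing)) {
    abort(paste0("truth id(s) not present in the ranking: ",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  truth
}

#' Ranks of the true DEGs in a ranking
#'
#' @param ranking a `deg_ranking`.
#' @param truth character vector of true DEG identifiers, all present in the
#'   ranking.
#' @return a tibble with columns `gene_id` and `rank` (1-based), one row per
#'   truth gene, sorted by rank.
#' @export
rank_of_true_degs <- function(ranking, truth) {
  truth <- check_truth(ranking, truth)
  out <- ranking[ranking$gene_id %in% truth, c("gene_id", "rank")]
  as_tibble(out[order(out$rank), ])
}

#' Confusion labels at a top-K cutoff
#'
#' Declares the top `k` ranked genes positive: a truth gene in the top `k`
#' is a TP, a non-truth gene there an FP; below the cutoff, truth genes are
#' FN and the rest TN. `TP + FN` always equals the truth-set size and
#' `TP + FP` equals `k`.
#'
#' @inheritParams rank_of_true_degs
#' @param k prediction cutoff, in `1..N`.
#' @return a tibble `gene_id`, `rank`, `label` with `label` in
#'   `{"TP","FP","FN","TN"}`, in rank order.
#' @export
confusion_labels <- function(ranking, truth, k) {
  truth <- check_truth(ranking, truth)
  n <- nrow(ranking)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n) {
    abort(sprintf("`k` must be in 1..%d.", n))
  }
  is_true <- ranking$gene_id %in% truth
  in_top <- ranking$rank <= k
  label <- ifelse(in_top,
                  ifelse(is_true, "TP", "FP"),
                  ifelse(is_true, "FN", "TN"))
  tibble(gene_id = ranking$gene_id, rank = ranking$rank, label = label)
}

#' Prefix ROC curve over top-K cutoffs
#'
#' One point per prediction-count cutoff `k = 0..min(k_max, N)`:
#' `TPR(k) = TP(k) / |truth|` and `FPR(k) = FP(k) / (N - |truth|)`. The
#' cutoff is a rank prefix, not a score threshold, because practitioners
#' verify a fixed number of top predictions.
#'
#' @inheritParams rank_of_true_degs
#' @param k_max largest cutoff (default 1000, the range over which gene
#'   lists are realistically followed up).
#' @return a tibble of class `deg_roc` with columns `k`, `tp`, `fp`, `tpr`,
#'   `fpr`, starting at (0, 0).
#' @export
roc_curve <- function(ranking, truth, k_max = 1000L) {
  truth <- check_truth(ranking, truth)
  n <- nrow(ranking)
  n_true <- length(truth)
  if (n - n_true < 1L) abort("ranking must contain at least one non-truth gene.")
  k_top <- min(k_max, n)
  hits <- cumsum(ranking$gene_id[seq_len(k_top)] %in% truth)
  k <- 0:k_top
  tp <- c(0L, hits)
  fp <- k - tp
  out <- tibble(k = k, tp = tp, fp = fp,
                tpr = tp / n_true, fpr = fp / (n - n_true))
  structure(out, class = c("deg_roc", class(out)),
            n = n, n_truth = n_true, k_max = k_top)
}

#' Unnormalised partial area under a prefix ROC curve
#'
#' Trapezoidal area under TPR as a function of FPR over the curve's points.
#' The area is left in raw FPR x TPR units (not rescaled to the visited FPR
#' range), so with a truth set of a few dozen genes among tens of thousands
#' and `k_max = 1000` typical magnitudes are a few hundredths.
#'
#' @param roc a `deg_roc` tibble (or any data frame with `fpr`, `tpr`
#'   columns ordered by cutoff).
#' @return the area, a single number in `[0, max(fpr)]`.
#' @export
partial_auc <- function(roc) {
  if (!is.data.frame(roc) || !all(c("fpr", "tpr") %in% names(roc))) {
    abort("`roc` must have `fpr` and `tpr` columns, as from `roc_curve()`.")
  }
  if (nrow(roc) < 2L) abort("need at least two ROC points.")
  dx <- diff(roc$fpr)
  mid <- (roc$tpr[-1L] + roc$tpr[-nrow(roc)]) / 2
  sum(dx * mid)
}

#' True-positive counts at a set of top-K cutoffs
#'
#' @inheritParams rank_of_true_degs
#' @param ks cutoffs, each in `1..N`. The defaults mirror the common
#'   reporting grid for prediction-budget comparisons.
#' @return a tibble `k`, `n_true`.
#' @export
topk_true_positives <- function(ranking, truth,
                                ks = c(150L, 250L, 350L, 450L, 550L)) {
  truth <- check_truth(ranking, truth)
  n <- nrow(ranking)
  if (any(ks < 1 | ks > n)) {
    abort(sprintf("all `ks` must be in 1..%d.", n))
  }
  is_true <- ranking$gene_id %in% truth
  hits <- cumsum(is_true)
  tibble(k = as.integer(ks), n_true = hits[as.integer(ks)])
}

#' Full evaluation of a ranking against a truth set
#'
#' Bundles the prefix ROC curve, its unnormalised partial AUC, top-K
#' true-positive counts, and the ranks of every truth gene.
#'
#' @inheritParams roc_curve
#' @inheritParams topk_true_positives
#' @return an object of class `deg_evaluation`: a list with elements `roc`,
#'   `partial_auc`, `topk`, `true_deg_ranks`, plus `method` and `mode`
#'   copied from the ranking.
#' @export
evaluate_ranking <- function(ranking, truth, k_max = 1000L,
                             ks = c(150L, 250L, 350L, 450L, 550L)) {
  ks <- ks[ks <= nrow(ranking)]
  if (!length(ks)) ks <- nrow(ranking)
  roc <- roc_curve(ranking, truth, k_max = k_max)
  structure(
    list(roc = roc,
         partial_auc = partial_auc(roc),
         topk = topk_true_positives(ranking, truth, ks = ks),
         true_deg_ranks = rank_of_true_degs(ranking, truth),
         method = attr(ranking, "method"),
         mode = attr(ranking, "mode")),
    class = "deg_evaluation"
  )
}

#' @export
print.deg_evaluation <- function(x, ...) {
  cat(sprintf("<deg_evaluation> method = %s (pruning mode = %s)\n",
              x$method %||% "?", x$mode))
  cat(sprintf("  partial AUC (k <= %d): %.6g\n", attr(x$roc, "k_max"), x$partial_auc))
  cat(sprintf("  top-K true positives: %s\n",
              paste(sprintf("%d@%d", x$topk$n_true, x$topk$k), collapse = ", ")))
  invisible(x)
}

#' @rdname evaluate_ranking
#' @param x a `deg_evaluation`.
#' @param ... unused.
#' @export
glance.deg_evaluation <- function(x, ...) {
  tibble(
    method = x$method %||% NA_character_,
    mode = x$mode,
    partial_auc = x$partial_auc,
    median_true_rank = stats::median(x$true_deg_ranks$rank),
    n_truth = attr(x$roc, "n_truth")
  )
}

#' @rdname evaluate_ranking
#' @export
tidy.deg_evaluation <- function(x, ...) {
  as_tibble(x$roc)
}
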