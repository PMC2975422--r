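#' Count fixed-radius neighbours in (AG, AD) space
#'
#' For each gene, counts the other genes whose Euclidean distance in the
#' (average expression, average difference) plane is strictly less than
#' `r0`. The relation is symmetric, a gene is never its own neighbour, and
#' points at distance exactly `r0` do not count — so `r0 = 0` always yields
#' zero counts. Coincident genes are mutual neighbours for any `r0 > 0`.
#'
#' The implementation sorts genes by `ag` and sweeps a window of width `r0`,
#' which is near-linear for the small radii typical of dense expression
#' clouds while remaining exactly equivalent to the quadratic definition,
#' including boundary ties.
#'
#' @param features a `deg_features` tibble (or any data frame with `ag` and
#'   `ad` columns).
#' @param r0 neighbour radius in feature units, `>= 0`.
#' @return integer vector of neighbour counts, one per gene, in input order.
#' @export
count_neighbors <- function(features, r0) {
  features <- as_features(features)
  if (!is.numeric(r0) || length(r0) != 1L || is.na(r0) || r0 < 0) {
    abort("`r0` must be a single non-negative number.")
  }
  count_neighbors_cpp(features$ag, features$ad, r0)
}

#' Density-based pruning of non-differential genes
#'
#' Removes genes with `n0` or more neighbours within radius `r0` in the
#' (AG, AD) feature space. Genes in the dense core — equally expressed in
#' both conditions — accumulate many neighbours and are pruned, while sparse
#' boundary genes (high expression, large between-condition difference,
#' where experimentally verified DEGs concentrate) survive as candidate
#' DEGs. Exactly one of `r0` and `target_k` must be supplied: with
#' `target_k`, the radius is chosen by [search_radius()] to leave close to
#' `target_k` survivors.
#'
#' @param features a `deg_features` tibble.
#' @param n0 density threshold: a gene is pruned iff its neighbour count is
#'   `>= n0`. Positive integer; 4 is a robust default across many datasets.
#' @param r0 neighbour radius in feature units.
#' @param target_k desired number of surviving candidate genes.
#' @param max_iter maximum bisection iterations when `target_k` is used.
#' @return a tibble of class `deg_pruning` with columns `gene_id`, `ag`,
#'   `ad`, `n_neighbors`, `kept`, in input gene order, carrying the
#'   parameters used as attributes `r0` and `n0`.
#' @seealso [search_radius()], [rank_genes()]
#' @export
#' @examples
#' sim <- simulate_deg_matrix(n_genes = 500, n_deg = 20, seed = 1)
#' feats <- compute_features(sim$matrix)
#' pr <- prune_genes(feats, n0 = 4, target_k = 100)
#' glance(pr)
prune_genes <- function(features, n0 = 4, r0 = NULL, target_k = NULL,
                        max_iter = 64L) {
  features <- as_features(features)
  if (!is.numeric(n0) || length(n0) != 1L || is.na(n0) || n0 < 1 || n0 != floor(n0)) {
    abort("`n0` must be a positive integer.")
  }
  if (is.null(r0) == is.null(target_k)) {
    abort("supply exactly one of `r0` or `target_k`.")
  }
  if (!is.null(target_k)) {
    return(search_radius(features, n0 = n0, target_k = target_k,
                         max_iter = max_iter)$result)
  }
  counts <- count_neighbors(features, r0)
  new_pruning(features, counts, r0 = r0, n0 = n0)
}

new_pruning <- function(features, counts, r0, n0) {
  out <- tibble(
    gene_id = features[["gene_id"]] %||% paste0("gene_", seq_len(nrow(features))),
    ag = features$ag,
    ad = features$ad,
    n_neighbors = counts,
    kept = counts < n0
  )
  structure(out, class = c("deg_pruning", class(out)), r0 = r0, n0 = n0)
}

#' Binary search for the radius yielding a target survivor count
#'
#' The survivor count is a non-increasing step function of the radius, so a
#' bisection over `r0` in `[0, max(ad)]` (radius 0 prunes nothing; beyond
#' the maximum AD value the count no longer responds on the difference
#' axis) locates the radius whose survivor count is closest to `target_k`.
#' Because the count is a step function the exact target may be
#' unattainable; among the radii visited, the closest count wins, with ties
#' broken toward more survivors, which errs on the side of keeping true
#' DEGs.
#'
#' @inheritParams prune_genes
#' @param target_k desired survivor count, in `1..N`.
#' @return a list with elements `r0` (the selected radius) and `result`
#'   (the corresponding `deg_pruning`).
#' @export
search_radius <- function(features, n0 = 4, target_k, max_iter = 64L) {
  features <- as_features(features)
  n <- nrow(features)
  if (!is.numeric(target_k) || length(target_k) != 1L || is.na(target_k) ||
      target_k < 1 || target_k > n) {
    abort(sprintf("`target_k` must be in 1..%d.", n))
  }
  eval_at <- function(r0) {
    counts <- count_neighbors(features, r0)
    list(r0 = r0, counts = counts, survivors = sum(counts < n0))
  }
  best <- NULL
  consider <- function(cand) {
    if (is.null(best)) return(cand)
    d_new <- abs(cand$survivors - target_k)
    d_old <- abs(best$survivors - target_k)
    if (d_new < d_old) return(cand)
    if (d_new == d_old && cand$survivors > best$survivors) return(cand)
    best
  }

  lo <- 0
  hi <- max(features$ad)
  cand <- eval_at(lo)            # r0 = 0: all survive
  best <- consider(cand)
  if (best$survivors != target_k && hi > lo) {
    cand <- eval_at(hi)
    best <- consider(cand)
    if (cand$survivors >= target_k) {
      # even the widest radius keeps >= target_k: hi is the best achievable end
      lo <- hi
    }
    iter <- 0L
    while (best$survivors != target_k && lo < hi && iter < max_iter) {
      mid <- (lo + hi) / 2
      cand <- eval_at(mid)
      best <- consider(cand)
      if (cand$survivors > target_k) lo <- mid else hi <- mid
      iter <- iter + 1L
    }
  }
  list(r0 = best$r0,
       result = new_pruning(features, best$counts, r0 = best$r0, n0 = n0))
}

#' @export
print.deg_pruning <- function(x, ...) {
  cat(sprintf("<deg_pruning> r0 = %g, n0 = %d: %d of %d genes kept\n",
              attr(x, "r0"), attr(x, "n0"), sum(x$kept), nrow(x)))
  NextMethod()
}

#' @rdname prune_genes
#' @param x a `deg_pruning` object.
#' @param ... unused.
#' @export
glance.deg_pruning <- function(x, ...) {
  tibble(
    r0 = attr(x, "r0"),
    n0 = attr(x, "n0"),
    n_genes = nrow(x),
    n_kept = sum(x$kept),
    n_pruned = sum(!x$kept),
    prop_pruned = mean(!x$kept)
  )
}

#' @rdname prune_genes
#' @export
tidy.deg_pruning <- function(x, ...) {
  as_tibble(x)
}
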