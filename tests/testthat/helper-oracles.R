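# Independent reference implementations used as test oracles.
# These deliberately use the naive quadratic / enumerative definitions and
# never share code with the package internals they check.

# O(N^2) fixed-radius neighbour counts: strict inequality on the squared
# Euclidean distance, self excluded.
brute_counts <- function(ag, ad, r0) {
  if (r0 <= 0) return(integer(length(ag)))
  d2 <- outer(ag, ag, "-")^2 + outer(ad, ad, "-")^2
  diag(d2) <- Inf
  as.integer(rowSums(d2 < r0^2))
}

brute_survivors <- function(ag, ad, r0, n0) {
  brute_counts(ag, ad, r0) < n0
}

# Exhaustive scan over all pairwise-distance midpoints for the best
# achievable |survivors - K| over r0 in [0, max(ad)]. A gene survives at
# radius r0 iff fewer than n0 of its distances are < r0, i.e. iff its
# n0-th nearest-neighbour distance is >= r0.
exhaustive_best_gap <- function(ag, ad, n0, target_k) {
  n <- length(ag)
  d <- as.matrix(stats::dist(cbind(ag, ad)))
  diag(d) <- Inf
  kth <- apply(d, 1L, function(z) sort(z)[n0])
  steps <- sort(unique(pmin(kth, Inf)))
  cands <- sort(unique(c(0, max(ad), steps,
                         steps - diff(c(0, steps)) / 2)))
  cands <- cands[cands >= 0 & cands <= max(ad)]
  counts <- vapply(cands, function(r0) sum(kth >= r0), numeric(1))
  min(abs(counts - target_k))
}

# Pooled two-sample t statistic, textbook form.
pooled_t <- function(a, b, floor = 0) {
  p1 <- length(a); p2 <- length(b)
  sp2 <- ((p1 - 1) * stats::var(a) + (p2 - 1) * stats::var(b)) / (p1 + p2 - 2)
  abs(mean(a) - mean(b)) / sqrt(sp2 * (1 / p1 + 1 / p2) + floor)
}

# Rank product by explicit enumeration of every ordered A-B sample pair:
# geometric means of descending (up) and ascending (down) average-tie ranks.
brute_rank_product <- function(values, a_idx, b_idx) {
  n <- nrow(values)
  up <- matrix(NA_real_, n, 0)
  down <- matrix(NA_real_, n, 0)
  for (ai in a_idx) {
    for (bi in b_idx) {
      dvec <- values[, bi] - values[, ai]
      up <- cbind(up, rank(-dvec, ties.method = "average"))
      down <- cbind(down, rank(dvec, ties.method = "average"))
    }
  }
  rp_up <- exp(rowMeans(log(up)))
  rp_down <- exp(rowMeans(log(down)))
  -log(pmin(rp_up, rp_down))
}

# Random point cloud mimicking a dense expression core plus sparse boundary.
random_cloud <- function(n, seed, n_boundary = round(n * 0.05)) {
  withr::with_seed(seed, {
    core <- n - n_boundary
    ag <- c(rnorm(core, 7, 1), rnorm(n_boundary, 9, 1.5))
    ad <- c(abs(rnorm(core, 0, 0.15)), runif(n_boundary, 1, 3))
    # a few exact duplicates to exercise coincident-point handling
    if (n >= 10) {
      ag[1:3] <- ag[4]
      ad[1:3] <- ad[4]
    }
    tibble::tibble(gene_id = paste0("g", seq_len(n)), ag = ag, ad = ad)
  })
}

# Small labelled matrix for IO / ranking fixtures.
tiny_matrix <- function(values, n_a, n_b, gene_ids = NULL) {
  values <- as.matrix(values)
  p <- n_a + n_b
  stopifnot(ncol(values) == p)
  sample_ids <- c(sprintf("A%d", seq_len(n_a)), sprintf("B%d", seq_len(n_b)))
  design <- group_design(stats::setNames(rep(c("A", "B"), c(n_a, n_b)),
                                         sample_ids))
  deg_matrix(values, design = design,
             gene_ids = gene_ids %||% paste0("g", seq_len(nrow(values))),
             sample_ids = sample_ids)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
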