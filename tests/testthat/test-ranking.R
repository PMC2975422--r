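test_that("fold change scores the absolute log ratio", {
  m <- tiny_matrix(rbind(c(2, 2, 4, 4),
                         c(3, 3, 3, 3)), 2, 2)
  f <- compute_features(m)
  s <- score_fold_change(f)
  expect_equal(s, c(2, 0))  # 2 log2 units = 4-fold change

  sim <- simulate_deg_matrix(n_genes = 300, n_deg = 30, seed = 6)
  fs <- compute_features(sim$matrix)
  expect_equal(score_fold_change(fs), abs(fs$mean_a - fs$mean_b),
               tolerance = 1e-12)
})

test_that("WAD weights AD by min-max-normalised AG", {
  f <- tibble::tibble(gene_id = paste0("g", 1:4),
                      ag = c(2, 5, 8, 8), ad = c(3, 1, 0.5, 2))
  s <- score_wad(f)
  expect_equal(s[1], 0)            # minimal ag: weight 0 regardless of ad
  expect_equal(s[3], 0.5)          # maximal ag: weight 1, score = ad
  expect_equal(s[4], 2)
  expect_equal(s, f$ad * (f$ag - 2) / 6, tolerance = 1e-12)

  flat <- tibble::tibble(ag = rep(4, 5), ad = 1:5 / 2)
  expect_equal(score_wad(flat), flat$ad)  # constant ag: weight 1 everywhere

  sim <- simulate_deg_matrix(n_genes = 100, n_deg = 10, seed = 12)
  fs <- compute_features(sim$matrix)
  w <- (fs$ag - min(fs$ag)) / (max(fs$ag) - min(fs$ag))
  expect_equal(score_wad(fs), fs$ad * w, tolerance = 1e-12)
})

test_that("the t score matches the textbook pooled statistic", {
  m <- tiny_matrix(rbind(c(1, 2, 3, 4, 5, 6),
                         c(2, 2, 2, 2, 2, 2)), 3, 3)
  s <- score_ttest(m, variance_floor = 1e-12)
  expect_equal(s[1], 3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(s[1], pooled_t(c(1, 2, 3), c(4, 5, 6), 1e-12), tolerance = 1e-12)
  expect_equal(s[2], 0)

  vals <- withr::with_seed(30, matrix(rnorm(50 * 9, 7), 50, 9))
  m2 <- tiny_matrix(vals, 4, 5)
  s2 <- score_ttest(m2, variance_floor = 1e-9)
  oracle <- vapply(seq_len(50), function(i) {
    pooled_t(vals[i, 1:4], vals[i, 5:9], 1e-9)
  }, numeric(1))
  expect_equal(s2, oracle, tolerance = 1e-10)

  welch <- score_ttest(m2, welch = TRUE)
  wor <- vapply(seq_len(50), function(i) {
    abs(t.test(vals[i, 1:4], vals[i, 5:9])$statistic)
  }, numeric(1))
  expect_equal(welch, unname(wor), tolerance = 1e-6)
})

test_that("zero-variance genes get finite, dominant t scores", {
  m <- tiny_matrix(rbind(c(2, 2, 3, 3),
                         c(1, 9, 3, 8)), 2, 2)
  s <- score_ttest(m, variance_floor = 1e-8)
  expect_true(is.finite(s[1]))
  expect_equal(s[1], 1 / sqrt(1e-8))
  expect_gt(s[1], s[2])
})

test_that("the t score refuses designs with a single-sample condition", {
  m <- tiny_matrix(matrix(rnorm(9, 7), 3, 3), 1, 2)
  expect_error(score_ttest(m), "fold change or rank product")
})

test_that("rank product matches enumeration of all pairwise rank lists", {
  vals <- rbind(c(5.0, 5.2, 8.1),
                c(7.0, 6.5, 6.8),
                c(3.1, 3.3, 3.0))
  m <- tiny_matrix(vals, 2, 1)
  expect_equal(score_rank_product(m),
               brute_rank_product(vals, 1:2, 3), tolerance = 1e-12)

  vals2 <- withr::with_seed(44, matrix(rnorm(5 * 6, 7), 5, 6))
  vals2[2, 4:6] <- vals2[2, 4:6] + 2
  m2 <- tiny_matrix(vals2, 3, 3)
  expect_equal(score_rank_product(m2),
               brute_rank_product(vals2, 1:3, 4:6), tolerance = 1e-12)
})

test_that("degenerate rank-product inputs behave as defined", {
  # single A-B pair with sign-symmetric differences: order agrees with FC
  vals <- cbind(c(7, 7, 7, 7, 7), c(12, 3, 10, 5, 8))  # d = 5,-4,3,-2,1
  m <- tiny_matrix(vals, 1, 1)
  rk_rp <- rank_genes(score_rank_product(m), m$gene_ids)
  rk_fc <- rank_genes(score_fold_change(compute_features(m)), m$gene_ids)
  expect_equal(rk_rp$gene_id, rk_fc$gene_id)

  # identical genes: every rank tied at (N+1)/2, all scores equal
  flat <- tiny_matrix(matrix(5, 4, 4), 2, 2)
  s <- score_rank_product(flat)
  expect_equal(s, rep(-log((4 + 1) / 2), 4))
})

test_that("rank_genes sorts stably and honours pruning modes", {
  rk <- rank_genes(c(3, 1, 2), gene_ids = c("a", "b", "c"))
  expect_equal(rk$gene_id, c("a", "c", "b"))
  expect_equal(rk$rank, 1:3)

  tie <- rank_genes(c(2, 2, 1), gene_ids = c("a", "b", "c"))
  expect_equal(tie$gene_id, c("a", "b", "c"))

  pruning <- structure(
    tibble::tibble(gene_id = c("a", "b", "c", "d"),
                   ag = 1:4 / 1, ad = 1:4 / 1,
                   n_neighbors = c(5L, 0L, 5L, 0L),
                   kept = c(FALSE, TRUE, FALSE, TRUE)),
    class = c("deg_pruning", class(tibble::tibble())), r0 = 1, n0 = 4)
  ap <- rank_genes(c(9, 1, 8, 2), pruning = pruning, mode = "append")
  expect_equal(ap$gene_id, c("d", "b", "a", "c"))  # survivors first
  expect_equal(ap$kept, c(TRUE, TRUE, FALSE, FALSE))

  ex <- rank_genes(c(9, 1, 8, 2), pruning = pruning, mode = "exclude")
  expect_equal(ex$gene_id, c("d", "b"))

  expect_error(rank_genes(c(1, NA, 2)), "finite")
  expect_error(rank_genes(c(1, Inf, 2)), "finite")
})

test_that("scores are permutation-equivariant and label-swap invariant", {
  sim <- simulate_deg_matrix(n_genes = 150, n_deg = 15, n_a = 4, n_b = 4,
                             seed = 19)
  x <- sim$matrix
  f <- compute_features(x)
  perm <- withr::with_seed(2, sample.int(150))
  xp <- deg_matrix(x$values[perm, ], design = x$design,
                   gene_ids = x$gene_ids[perm], sample_ids = x$sample_ids)
  fp <- compute_features(xp)
  expect_equal(score_wad(fp), score_wad(f)[perm], tolerance = 1e-12)
  expect_equal(score_ttest(xp), score_ttest(x)[perm], tolerance = 1e-12)
  expect_equal(score_rank_product(xp), score_rank_product(x)[perm],
               tolerance = 1e-12)

  swapped <- set_design(x, stats::setNames(ifelse(x$design == "A", "B", "A"),
                                           x$sample_ids))
  fsw <- compute_features(swapped)
  expect_equal(score_fold_change(fsw), score_fold_change(f))
  expect_equal(score_wad(fsw), score_wad(f))
  expect_equal(score_ttest(swapped), score_ttest(x), tolerance = 1e-12)
})

test_that("append-mode pruning never worsens the rank of a kept true DEG", {
  sim <- simulate_deg_matrix(n_genes = 1500, n_deg = 30, seed = 23)
  f <- compute_features(sim$matrix)
  pr <- prune_genes(f, n0 = 4, target_k = 300)
  for (method in c("fc", "ttest", "wad")) {
    rk0 <- rank_degs(sim$matrix, method, features = f)
    rk1 <- rank_degs(sim$matrix, method, features = f, pruning = pr,
                     mode = "append")
    kept_truth <- intersect(sim$truth, pr$gene_id[pr$kept])
    r0 <- rank_of_true_degs(rk0, kept_truth)
    r1 <- rank_of_true_degs(rk1, kept_truth)
    both <- merge(r0, r1, by = "gene_id")
    expect_true(all(both$rank.y <= both$rank.x))
  }
})
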