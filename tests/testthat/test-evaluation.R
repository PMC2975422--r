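ranking_from_ids <- function(ids, scores = rev(seq_along(ids))) {
  rank_genes(scores, gene_ids = ids)
}

test_that("enrichment is the truth fraction of a list, with guarded inputs", {
  expect_equal(enrichment_score(10, 100), 0.1)
  expect_equal(enrichment_score(0, 50), 0)
  expect_error(enrichment_score(5, 4), "between 0")
  expect_error(enrichment_score(1, 0), "at least 1")
})

test_that("true-DEG ranks are 1-based positions in the ranking", {
  rk <- ranking_from_ids(paste0("g", 1:10))
  top <- rank_of_true_degs(rk, "g1")
  expect_equal(top$rank, 1L)
  expect_equal(rank_of_true_degs(rk, "g7")$rank, 7L)
  expect_equal(rank_of_true_degs(rk, c("g7", "g2"))$gene_id, c("g2", "g7"))
  expect_error(rank_of_true_degs(rk, "nope"), "not present")
})

test_that("confusion labels satisfy the accounting identities", {
  rk <- ranking_from_ids(paste0("g", 1:20))
  truth <- c("g1", "g5", "g15")
  for (k in c(1, 4, 10, 20)) {
    lab <- confusion_labels(rk, truth, k)
    counts <- table(factor(lab$label, levels = c("TP", "FP", "FN", "TN")))
    expect_equal(unname(counts["TP"] + counts["FN"]), length(truth))
    expect_equal(unname(counts["TP"] + counts["FP"]), k)
    expect_equal(sum(counts), 20)
  }
  at_n <- confusion_labels(rk, truth, 20)
  expect_setequal(unique(at_n$label), c("TP", "FP"))
  expect_error(confusion_labels(rk, truth, 0), "k")
  expect_error(confusion_labels(rk, truth, 21), "k")
})

test_that("prefix ROC hits the perfect and inverted extremes", {
  ids <- paste0("g", 1:100)
  truth <- paste0("g", 1:5)
  perfect <- ranking_from_ids(ids)
  roc <- roc_curve(perfect, truth, k_max = 100)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[roc$k == 5], 1)
  expect_equal(roc$fpr[roc$k == 5], 0)
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))

  inverted <- ranking_from_ids(rev(ids))
  roci <- roc_curve(inverted, truth, k_max = 100)
  expect_true(all(roci$tpr[roci$k <= 95] == 0))
  expect_equal(roci$tpr[roci$k == 100], 1)

  expect_error(roc_curve(perfect, character(), k_max = 10), "non-empty")
})

test_that("a random ranking tracks the diagonal in expectation", {
  ids <- paste0("g", 1:50)
  truth <- paste0("g", c(3, 11, 24, 37, 45))
  tpr25 <- vapply(1:1000, function(s) {
    shuffled <- withr::with_seed(s, sample(ids))
    roc <- roc_curve(ranking_from_ids(shuffled), truth, k_max = 50)
    roc$tpr[roc$k == 25]
  }, numeric(1))
  # E[TPR(k)] = k/N; MC standard error ~ 0.007 at 1000 draws
  expect_lt(abs(mean(tpr25) - 0.5), 0.03)
})

test_that("partial AUC equals a hand trapezoid and respects its bounds", {
  # 10 genes, truth = {g1, g3}, ranking g1..g10:
  # hits at k = 1 and 3; FPR steps of 1/8 at the non-truth ks
  rk <- ranking_from_ids(paste0("g", 1:10))
  truth <- c("g1", "g3")
  roc <- roc_curve(rk, truth, k_max = 10)
  # hand trapezoid: TPR is 0.5 over FPR [0, 1/8], then 1.0 over [1/8, 1]
  expect_equal(partial_auc(roc), 0.5 * (1 / 8) + 1 * (7 / 8))

  # perfect ranking: area = full FPR range at TPR 1
  perfect <- roc_curve(ranking_from_ids(paste0("g", 1:100)),
                       paste0("g", 1:5), k_max = 100)
  expect_equal(partial_auc(perfect), 1)

  # no true positives inside the cutoff: zero area
  late <- roc_curve(ranking_from_ids(paste0("g", 1:100)), "g100", k_max = 50)
  expect_equal(partial_auc(late), 0)

  # bound: 0 <= area <= FPR(k_max)
  for (s in 1:10) {
    shuffled <- withr::with_seed(s, sample(paste0("g", 1:60)))
    roc_s <- roc_curve(ranking_from_ids(shuffled), paste0("g", 1:6), k_max = 30)
    a <- partial_auc(roc_s)
    expect_gte(a, 0)
    expect_lte(a, max(roc_s$fpr))
  }
})

test_that("moving a truth gene up never decreases the partial AUC", {
  ids <- paste0("g", 1:40)
  truth <- c("g30", "g35")
  base <- partial_auc(roc_curve(ranking_from_ids(ids), truth, k_max = 40))
  swapped <- ids
  swapped[c(10, 30)] <- swapped[c(30, 10)]  # truth gene moves above non-truth
  up <- partial_auc(roc_curve(ranking_from_ids(swapped), truth, k_max = 40))
  expect_gte(up, base)
})

test_that("top-K counts agree with confusion labels and are monotone", {
  sim <- simulate_deg_matrix(n_genes = 400, n_deg = 25, seed = 31)
  rk <- rank_degs(sim$matrix, "wad")
  ks <- c(10L, 50L, 150L, 400L)
  tk <- topk_true_positives(rk, sim$truth, ks = ks)
  expect_true(all(diff(tk$n_true) >= 0))
  expect_true(all(tk$n_true <= pmin(tk$k, length(sim$truth))))
  for (i in seq_along(ks)) {
    lab <- confusion_labels(rk, sim$truth, ks[i])
    expect_equal(tk$n_true[i], sum(lab$label == "TP"))
  }
  expect_equal(topk_true_positives(rk, sim$truth, ks = 400L)$n_true, 25L)
  expect_error(topk_true_positives(rk, sim$truth, ks = 401L), "ks")

  perfect <- ranking_from_ids(paste0("g", 1:200))
  expect_equal(topk_true_positives(perfect, paste0("g", 1:7), ks = 150L)$n_true, 7L)
  expect_equal(topk_true_positives(perfect, "g60", ks = 50L)$n_true, 0L)
})

test_that("evaluate_ranking bundles consistent pieces", {
  sim <- simulate_deg_matrix(n_genes = 300, n_deg = 20, seed = 37)
  rk <- rank_degs(sim$matrix, "fc")
  ev <- evaluate_ranking(rk, sim$truth, k_max = 200, ks = c(50L, 150L))
  expect_s3_class(ev, "deg_evaluation")
  expect_equal(ev$partial_auc, partial_auc(ev$roc))
  expect_equal(ev$topk$n_true,
               topk_true_positives(rk, sim$truth, c(50L, 150L))$n_true)
  expect_equal(nrow(ev$true_deg_ranks), 20)
  g <- glance(ev)
  expect_equal(g$partial_auc, ev$partial_auc)
})
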