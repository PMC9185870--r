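test_that("MCC matches the closed form and its degenerate convention", {
  expect_equal(mcc(10, 0, 90, 0), 1)
  expect_equal(mcc(0, 0, 90, 10), 0)
  tp <- 6; fp <- 2; tn <- 88; fn <- 4
  byhand <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(mcc(tp, fp, tn, fn), byhand)
  # symmetry under simultaneous class-and-prediction relabeling
  set.seed(6)
  for (i in 1:20) {
    cc <- sample(0:30, 4, replace = TRUE) + 1
    expect_equal(mcc(cc[1], cc[2], cc[3], cc[4]),
                 mcc(cc[3], cc[4], cc[1], cc[2]))
  }
})

test_that("F1 and accuracy follow their formulas", {
  perfect <- f1_accuracy(10, 0, 90, 0)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(f1_accuracy(0, 0, 90, 10)$f1, 0)
  fa <- f1_accuracy(6, 2, 88, 4)
  expect_equal(fa$f1, 2 * 6 / (2 * 6 + 2 + 4))
  expect_equal(fa$accuracy, 94 / 100)
})

test_that("curve areas behave at the extremes", {
  sep <- roc_pr_curves(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$auroc, 1)
  expect_equal(sep$aupr, 1)

  const <- roc_pr_curves(rep(0.5, 100), c(rep(1, 5), rep(0, 95)))
  expect_equal(const$aupr, 0.05)
  expect_equal(const$auroc, 0.5)

  expect_error(roc_pr_curves(runif(5), rep(1, 5)), "single class")
})

test_that("auROC equals the normalized Mann-Whitney U statistic", {
  set.seed(19)
  for (i in 1:10) {
    n <- 20
    labels <- sample(c(rep(1, 7), rep(0, 13)))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    curves <- roc_pr_curves(scores, labels)
    r <- rank(scores)  # midranks
    n_pos <- sum(labels); n_neg <- n - n_pos
    u <- sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2
    expect_equal(curves$auroc, u / (n_pos * n_neg))
  }
})

test_that("precision at full recall equals prevalence", {
  set.seed(23)
  scores <- runif(200)
  labels <- as.integer(runif(200) < 0.2)
  labels[1] <- 1; labels[2] <- 0
  curves <- roc_pr_curves(scores, labels)
  full <- curves$pr[curves$pr$recall == 1, ]
  expect_equal(full$precision[nrow(full)], mean(labels))
})

test_that("cutoff selection maximizes MCC with deterministic ties", {
  labels <- c(1, 1, 0, 0, 1, 0)
  expect_equal(choose_cutoff(labels, labels), 0.01)
  expect_equal(choose_cutoff(), 0.4)

  set.seed(14)
  post <- runif(6)
  best <- choose_cutoff(post, labels)
  grid <- seq(0, 1, by = 0.01)
  brute <- vapply(grid, function(ct) {
    cc <- confusion_counts(post >= ct, labels == 1)
    mcc(cc$tp, cc$fp, cc$tn, cc$fn)
  }, numeric(1))
  expect_equal(best, grid[which.max(brute)])
  # never worse than the preset cutoff on the tuning data
  cc_best <- confusion_counts(post >= best, labels == 1)
  cc_preset <- confusion_counts(post >= 0.4, labels == 1)
  expect_gte(mcc(cc_best$tp, cc_best$fp, cc_best$tn, cc_best$fn),
             mcc(cc_preset$tp, cc_preset$fp, cc_preset$tn, cc_preset$fn))
})

test_that("evaluation reports split by chromosome or pool", {
  set.seed(2)
  preds <- tibble::tibble(
    chrom = rep(c("chr1", "chr2"), each = 100),
    posterior = runif(200),
    bound = as.integer(runif(200) < 0.1))
  preds$bound[c(1, 101)] <- 1L
  rep_chrom <- evaluate_predictions(preds, cutoff = 0.4)
  expect_equal(nrow(rep_chrom), 2)
  expect_equal(rep_chrom$prevalence,
               c(mean(preds$bound[1:100]), mean(preds$bound[101:200])))
  pooled <- evaluate_predictions(preds, cutoff = 0.4, mode = "pooled")
  expect_equal(nrow(pooled), 1)
  expect_true(all(pooled$aupr >= 0 & pooled$aupr <= 1))
})

test_that("co-cluster Jaccard counts shared pairs", {
  a <- c(a = 1, b = 1, c = 2, d = 2)
  expect_equal(jaccard_coclusters(a, a), 1)
  b <- c(a = 1, c = 1, b = 2, d = 2)
  expect_equal(jaccard_coclusters(a, b), 0)
  abc <- c(a = 1, b = 1, c = 1)
  ab_c <- c(a = 1, b = 1, c = 2)
  expect_equal(jaccard_coclusters(abc, ab_c), 1 / 3)
  expect_equal(jaccard_coclusters(ab_c, abc), 1 / 3)  # symmetric
  singletons <- c(a = 1, b = 2, c = 3)
  expect_equal(jaccard_coclusters(singletons, singletons), 1)
  expect_error(jaccard_coclusters(c(a = 1), c(a = 1)), "2 items")
  expect_error(jaccard_coclusters(a, abc), "different items")
})

test_that("stability selection distinguishes planted blocks from noise", {
  set.seed(33)
  n <- 24
  block <- rep(1:2, each = n / 2)
  corr <- outer(block, block, function(i, j) ifelse(i == j, 0.9, -0.1))
  diag(corr) <- 1
  corr <- corr + matrix(rnorm(n * n, sd = 0.02), n)
  corr <- (corr + t(corr)) / 2
  rownames(corr) <- colnames(corr) <- paste0("tf", 1:n)
  res <- cluster_stability_select(corr, k_range = 2:6, repeats = 20, seed = 5)
  stab <- res$stability
  expect_gte(stab$jaccard_data[stab$k == 2], 0.95)
  expect_gte(stab$jaccard_data[stab$k == 2] -
               stab$jaccard_control[stab$k == 2], 0.3)

  # deterministic given the seed
  res2 <- cluster_stability_select(corr, k_range = 2:6, repeats = 20, seed = 5)
  expect_equal(res$stability, res2$stability)
  expect_equal(res$k, res2$k)

  # forced identical subsamples give perfect stability at every k
  res3 <- cluster_stability_select(corr, k_range = 2:4, subsample = 1,
                                   repeats = 1, seed = 1)
  expect_equal(res3$stability$jaccard_data, rep(1, 3))

  expect_error(cluster_stability_select(corr[1:3, 1:3]), "4 items")
})
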