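test_that("confusion counts by definition and flips under label swap", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(unlist(unclass(cm)), c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_identical(perfect$fp + perfect$fn, 0L)
  # swapping the label convention swaps tp<->tn, fp<->fn
  t <- c(1, 1, 0, 0, 1); e <- c(1, 0, 0, 1, 1)
  a <- confusion(t, e); b <- confusion(1 - t, 1 - e)
  expect_identical(c(a$tp, a$fp), c(b$tn, b$fn))
  expect_error(confusion(c(1, 0), c(1)), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("metrics reproduce the hand-evaluated confusion table", {
  m <- metrics(list(tp = 40, fn = 10, tn = 45, fp = 5))
  expect_equal(m$acc, 0.85)
  expect_equal(m$sens, 0.8)
  expect_equal(m$spec, 0.9)
  expect_equal(m$pre, 8 / 9)
  expect_equal(m$f_score, 0.8421, tolerance = 1e-4)
  expect_equal(m$mcc, 0.7035, tolerance = 1e-4)

  perfect <- metrics(list(tp = 50, tn = 50, fp = 0, fn = 0))
  expect_equal(perfect[, c("acc", "mcc", "f_score")],
               tibble::tibble(acc = 1, mcc = 1, f_score = 1))
})

test_that("f-score at beta 1 is the harmonic mean of precision and sensitivity", {
  set.seed(5)
  for (i in 1:100) {
    cm <- list(tp = rpois(1, 20), fp = rpois(1, 10),
               tn = rpois(1, 20), fn = rpois(1, 10))
    if (sum(unlist(cm)) == 0) next
    m <- metrics(cm)
    hm <- if (m$pre + m$sens > 0) 2 * m$pre * m$sens / (m$pre + m$sens) else 0
    expect_equal(m$f_score, hm)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
  }
})

test_that("mcc equals the Pearson correlation of the label vectors", {
  set.seed(6)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    truth <- rbinom(n, 1, 0.5)
    est <- rbinom(n, 1, 0.5)
    cm <- confusion(truth, est)
    den <- (cm$tp + cm$fp) * (cm$tp + cm$fn) * (cm$tn + cm$fp) * (cm$tn + cm$fn)
    if (den == 0) next  # degenerate: package reports 0, correlation is NA
    expect_equal(metrics(cm)$mcc, suppressWarnings(cor(truth, est)),
                 tolerance = 1e-12)
  }
})

test_that("mcc of random labels is centred at zero", {
  set.seed(7)
  mccs <- replicate(300, {
    metrics(confusion(rbinom(40, 1, 0.5), rbinom(40, 1, 0.5)))$mcc
  })
  expect_lt(abs(mean(mccs)), 0.03)
})

test_that("degenerate denominators fall back to zero", {
  all_pos <- metrics(list(tp = 5, fn = 0, tn = 0, fp = 0))
  expect_equal(all_pos$spec, 0)   # tn + fp == 0
  expect_equal(all_pos$mcc, 0)
  none_pred <- metrics(list(tp = 0, fn = 3, tn = 4, fp = 0))
  expect_equal(none_pred$pre, 0)
  expect_equal(none_pred$f_score, 0)
})

test_that("roc sweeps thresholds into the exact step curve", {
  pts <- roc_points(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(auc(pts), 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[nrow(pts)], 1)
  # symmetry: negating scores reflects the curve
  s <- c(0.3, 0.6, 0.2, 0.8, 0.5); l <- c(0, 1, 0, 1, 1)
  expect_equal(auc(roc_points(s, l)), 1 - auc(roc_points(-s, l)))
  expect_error(roc_points(c(1, 2), c(1, 1)), "both classes")
})

test_that("auc equals the normalized Mann-Whitney U statistic", {
  set.seed(8)
  for (i in 1:100) {
    n1 <- sample(5:20, 1); n0 <- sample(5:20, 1)
    scores <- round(c(rnorm(n1, 0.5), rnorm(n0)), 1)  # ties on purpose
    labels <- rep(c(1, 0), c(n1, n0))
    w <- suppressWarnings(
      wilcox.test(scores[labels == 1], scores[labels == 0]))$statistic
    expect_equal(auc(roc_points(scores, labels)), unname(w) / (n1 * n0),
                 tolerance = 1e-12)
  }
})

test_that("auc on label-independent scores is near one half", {
  set.seed(9)
  scores <- rnorm(2000)
  labels <- rbinom(2000, 1, 0.5)
  expect_lt(abs(auc(roc_points(scores, labels)) - 0.5), 0.05)
})

test_that("stratified folds partition ids with balanced classes", {
  ids <- sprintf("s%03d", 1:95)
  labels <- rep(c(0L, 1L), c(50, 45))
  f <- stratified_kfold(ids, labels, k = 10, seed = 3)
  expect_setequal(f$id, ids)
  expect_identical(anyDuplicated(f$id), 0L)
  per_fold <- table(f$fold, f$label)
  expect_true(all(abs(per_fold[, "0"] - 5) <= 1))
  expect_true(all(abs(per_fold[, "1"] - 4.5) <= 0.5))
  # deterministic given the seed
  expect_identical(f, stratified_kfold(ids, labels, k = 10, seed = 3))
  expect_error(stratified_kfold(ids[1:5], labels[1:5], k = 10), "exceeds")
  expect_error(stratified_kfold(ids, rep(1L, 95), k = 5), "both classes")
})

test_that("cross_validate runs the fold-scoped pipeline and aggregates metrics", {
  feats <- synth_features(n_per_class = 60, seed = 19)
  cv <- cross_validate(feats, classifier = "svm", k = 5, d_out = 20, seed = 2)
  td <- generics::tidy(cv)
  expect_identical(nrow(td), 5L)
  g <- generics::glance(cv)
  expect_equal(g$acc, mean(td$acc))
  expect_equal(g$auc, mean(td$auc))
  # folds partition all ids
  expect_setequal(cv$folds$id, feats$id)
  expect_setequal(cv$predictions$id, feats$id)
  # good recovery at the default signal level
  expect_gte(g$acc, 0.85)
})

test_that("repeated training flags a planted mislabeled point as stable", {
  fx <- separable_features(n_per_class = 30, sep = 3, seed = 23)
  d <- tibble::tibble(id = sprintf("p%02d", seq_len(nrow(fx$X))), label = fx$y)
  d <- dplyr::bind_cols(d, tibble::as_tibble(fx$X))
  d$label[1] <- 1L  # plant: a class-0 point labeled positive
  res <- stable_misclassifications(d, classifier = "svm", n_models = 20,
                                   threshold = 10, k = 5, d_out = 10, seed = 3)
  expect_true("p01" %in% res$stable_fn)   # labeled 1, predicted 0 repeatedly
  expect_length(intersect(res$stable_fp, res$stable_fn), 0L)
  # threshold = n_models empties both sets
  res2 <- stable_misclassifications(d, classifier = "svm", n_models = 3,
                                    threshold = 3, k = 5, d_out = 10, seed = 3)
  expect_length(res2$stable_fp, 0L)
  expect_length(res2$stable_fn, 0L)
})
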