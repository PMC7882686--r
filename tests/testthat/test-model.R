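test_that("conv_output_length matches brute-force window enumeration", {
  expect_identical(conv_output_length(80, 3, 2), 39L)
  expect_identical(conv_output_length(10, 4, 2), 4L)
  cases <- expand.grid(L = 1:50, F = 1:50, S = 1:4)
  cases <- cases[cases$F <= cases$L, ]
  got <- mapply(conv_output_length, cases$L, cases$F, cases$S)
  oracle <- mapply(function(L, F, S) length(seq(1L, L - F + 1L, by = S)),
                   cases$L, cases$F, cases$S)   # enumerate valid window starts
  expect_identical(got, oracle)
  expect_identical(conv_output_length(7, 7, 3), 1L)
  expect_error(conv_output_length(2, 3, 1), "shorter")
})

test_that("the default architecture is 5 conv x 32 filters with a sigmoid head", {
  mc <- default_dcnn(80)
  expect_identical(mc$n_conv, 5L)
  expect_identical(mc$filters, rep(32L, 5L))
  expect_identical(mc$pool_positions, c(2L, 4L))
  expect_identical(mc$conv_stride, 2L)
  expect_identical(mc$pool_stride, 2L)
  expect_identical(mc$head, "sigmoid1")
  expect_identical(mc$fc_sizes[length(mc$fc_sizes)], 1L)
  # 5 conv + 2 fc weight layers
  set.seed(1)
  params <- rtcp:::init_params(mc)
  expect_identical(sum(grepl("^(conv|fc)[0-9]+_W$", names(params))), 7L)
})

test_that("the small preset uses filters 16,16,32,32 and fc 13,2 softmax", {
  mc <- small_dcnn(80)
  expect_identical(mc$filters, c(16L, 16L, 32L, 32L))
  expect_identical(mc$fc_sizes, c(13L, 2L))
  expect_identical(mc$head, "softmax2")
  expect_error(default_dcnn(4), ">= 8")
})

test_that("analytic gradients agree with central differences", {
  mc <- tiny_dcnn()
  set.seed(7)
  params <- rtcp:::init_params(mc)
  bn <- rtcp:::init_bn_state(mc)
  X <- matrix(rnorm(5 * 12), 5, 12)
  y <- c(1, 0, 1, 1, 0)
  fw <- rtcp:::dcnn_forward(mc, params, bn, X, train = TRUE)
  grads <- rtcp:::dcnn_backward(mc, params, fw, y)
  loss_at <- function(p) {
    rtcp:::cross_entropy_loss(rtcp:::dcnn_forward(mc, p, bn, X, train = TRUE)$probs, y)
  }
  eps <- 1e-6
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      # conv biases are cancelled by batch-norm: both gradients ~ 0 there,
      # so compare on an absolute-plus-relative scale
      expect_lt(abs(num - grads[[nm]][i]), 1e-5 + 1e-4 * abs(num))
    }
  }
})

test_that("training separates a strongly separated two-Gaussian fixture", {
  fx <- separable_features(n_per_class = 60, sep = 2, seed = 21)
  fit <- train_dcnn(fx$X, fx$y, train = train_config(epochs = 25, seed = 5))
  expect_s3_class(fit, "rtcp_dcnn")
  expect_identical(nrow(fit$history), 25L)
  expect_gte(utils::tail(fit$history$train_acc, 1), 0.99)
  expect_gte(mean((predict_proba(fit, fx$X) >= 0.5) == (fx$y == 1)), 0.99)
  # loss decreases on average (early third vs final third)
  l <- fit$history$train_loss
  expect_lt(mean(utils::tail(l, 8)), mean(utils::head(l, 8)))
})

test_that("training is reproducible and robust to row permutation", {
  fx <- separable_features(n_per_class = 40, sep = 2, seed = 31)
  tc <- train_config(epochs = 12, seed = 9)
  f1 <- train_dcnn(fx$X, fx$y, train = tc)
  f2 <- train_dcnn(fx$X, fx$y, train = tc)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$params, f2$params)

  set.seed(4)
  perm <- sample(nrow(fx$X))
  f3 <- train_dcnn(fx$X[perm, ], fx$y[perm], train = tc)
  a1 <- mean((predict_proba(f1, fx$X) >= 0.5) == (fx$y == 1))
  a3 <- mean((predict_proba(f3, fx$X) >= 0.5) == (fx$y == 1))
  expect_lt(abs(a1 - a3), 0.01 + 1e-9)
})

test_that("prediction contracts: probabilities bounded, thresholds honoured, widths checked", {
  fx <- separable_features(n_per_class = 20, seed = 41)
  fit <- train_dcnn(fx$X, fx$y, train = train_config(epochs = 5, seed = 2))
  p <- predict_proba(fit, fx$X)
  expect_true(all(is.finite(p) & p >= 0 & p <= 1))
  expect_true(all(predict_label(fit, fx$X, threshold = 0) == 1L))
  expect_error(predict_proba(fit, fx$X[, 1:10]), "feature columns")
  expect_error(train_dcnn(fx$X, fx$y, train = train_config(epochs = 0)), ">= 1")
  expect_error(train_dcnn(fx$X, c(fx$y[-1], 2L)), "binary")
})

test_that("the softmax-head small network trains on separable data", {
  fx <- separable_features(n_per_class = 40, sep = 2.5, seed = 51)
  fit <- train_dcnn(fx$X, fx$y, config = small_dcnn(80),
                    train = train_config(epochs = 25, seed = 3))
  expect_gte(mean(predict_label(fit, fx$X) == fx$y), 0.97)
})

test_that("the learning-rate schedule steps down by the decay factor", {
  tc <- train_config()
  expect_equal(learning_rate_at(tc, c(0, 99, 100, 199, 250)),
               c(1e-3, 1e-3, 1e-4, 1e-4, 1e-5))
  fx <- separable_features(n_per_class = 15, seed = 61)
  fit <- train_dcnn(fx$X, fx$y,
                    train = train_config(epochs = 7, lr_decay_every = 3, seed = 1))
  expect_equal(fit$history$lr, 1e-3 * 0.1^(0:6 %/% 3))
  expect_error(train_config(lr_decay_factor = 0), "lr_decay_factor")
})

test_that("baselines fit the separable fixture and honour parameter overrides", {
  fx <- separable_features(n_per_class = 50, sep = 2, seed = 71)
  for (kind in c("svm", "rf", "ann", "nb")) {
    fit <- train_baseline(fx$X, fx$y, kind = kind, seed = 3)
    acc <- mean((predict_proba(fit, fx$X) >= 0.5) == (fx$y == 1))
    expect_gte(acc, 0.99)
  }
  rf <- train_baseline(fx$X, fx$y, kind = "rf", ntree = 13L, seed = 3)
  expect_identical(rf$fit$ntree, 13L)
  expect_error(train_baseline(fx$X, fx$y, kind = "lda"))
})

test_that("naive Bayes on a zero-signal fixture stays near chance", {
  set.seed(81)
  X <- matrix(rnorm(200 * 10), 200, 10)
  colnames(X) <- paste0("pc", 1:10)
  y <- rep(c(0L, 1L), each = 100)
  fit <- train_baseline(X, y, kind = "nb", seed = 1)
  set.seed(82)
  Xnew <- matrix(rnorm(400 * 10), 400, 10)
  colnames(Xnew) <- paste0("pc", 1:10)
  acc <- mean((predict_proba(fit, Xnew) >= 0.5) == rep(c(0, 1), 200))
  # 99% binomial interval around 0.5 at n = 400
  expect_lt(abs(acc - 0.5), 2.576 * sqrt(0.25 / 400) + 0.01)
})
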