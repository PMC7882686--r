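#' Confusion counts of a binary prediction
#'
#' @param truth,estimate Equal-length binary 0/1 vectors (1 = positive).
#' @return An `rtcp_confusion`: integer fields `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion <- function(truth, estimate) {
  truth <- as.integer(truth); estimate <- as.integer(estimate)
  if (length(truth) != length(estimate)) abort("truth and estimate differ in length")
  if (length(truth) == 0L) abort("empty label vectors")
  if (!all(c(truth, estimate) %in% c(0L, 1L))) abort("labels must be binary 0/1")
  structure(list(tp = sum(truth == 1L & estimate == 1L),
                 fp = sum(truth == 0L & estimate == 1L),
                 tn = sum(truth == 0L & estimate == 0L),
                 fn = sum(truth == 1L & estimate == 0L)),
            class = "rtcp_confusion")
}

#' @export
print.rtcp_confusion <- function(x, ...) {
  cat(sprintf("<confusion: tp=%d fp=%d tn=%d fn=%d>\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Classification metrics from a confusion table
#'
#' Accuracy, specificity, sensitivity, precision, F-score and Matthews
#' correlation coefficient:
#' \deqn{Acc = (TP+TN)/(TP+FP+TN+FN)}
#' \deqn{Spec = TN/(TN+FP), \quad Sens = TP/(TP+FN), \quad Pre = TP/(TP+FP)}
#' \deqn{F = (1+\beta^2)\, Pre \cdot Sens / (\beta^2 (Pre + Sens))}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' With `beta = 1` (the default) the F-score is the harmonic mean of
#' precision and sensitivity. Degenerate denominators yield 0 for the
#' affected metric, so cross-validation aggregation stays total.
#'
#' @param counts An `rtcp_confusion`, or a data frame/list with fields
#'   `tp`, `fp`, `tn`, `fn`.
#' @param beta Relative weight of sensitivity versus precision in the
#'   F-score.
#' @return A one-row tibble: `acc`, `spec`, `sens`, `pre`, `f_score`,
#'   `mcc`, `beta`.
#' @export
#' @examples
#' metrics(confusion(rep(c(1, 0), c(50, 55)),
#'                   rep(c(1, 0, 0, 1), c(40, 10, 45, 5))))
metrics <- function(counts, beta = 1) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  n <- tp + fp + tn + fn
  if (n < 1) abort("empty confusion table")
  safe_div <- function(num, den) if (den > 0) num / den else 0
  acc <- (tp + tn) / n
  spec <- safe_div(tn, tn + fp)
  sens <- safe_div(tp, tp + fn)
  pre <- safe_div(tp, tp + fp)
  f_score <- if (pre + sens > 0) {
    (1 + beta^2) * pre * sens / (beta^2 * (pre + sens))
  } else 0
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / sqrt(mcc_den) else 0
  tibble(acc = acc, spec = spec, sens = sens, pre = pre,
         f_score = f_score, mcc = mcc, beta = beta)
}

#' ROC curve and area under it
#'
#' `roc_points()` sweeps every distinct score (plus infinite endpoints) as
#' a decision threshold, predicting positive when `score >= threshold`;
#' tied scores share a point, giving the exact step curve. `auc()`
#' integrates it by the trapezoid rule.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Binary 0/1 truth; both classes must be present.
#' @return `roc_points()`: a tibble (`threshold`, `fpr`, `tpr`) ordered by
#'   increasing `fpr`; `auc()`: a number in `[0, 1]`.
#' @export
#' @examples
#' pts <- roc_points(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' auc(pts)  # 1
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  if (!all(labels %in% c(0L, 1L))) abort("labels must be binary 0/1")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) abort("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- purrr::map_dfr(thr, function(t) {
    pred_pos <- scores >= t
    tibble(threshold = t,
           fpr = sum(pred_pos & labels == 0L) / n_neg,
           tpr = sum(pred_pos & labels == 1L) / n_pos)
  })
  dplyr::arrange(pts, .data$fpr, .data$tpr)
}

#' @rdname roc_points
#' @param points A tibble from `roc_points()` (or anything with `fpr`,
#'   `tpr` columns ordered by `fpr`).
#' @export
auc <- function(points) {
  fpr <- points$fpr; tpr <- points$tpr
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Stratified k-fold assignment
#'
#' Splits sample ids into `k` folds preserving class proportions (each
#' class is shuffled with the given seed and dealt round-robin), so fold
#' class counts differ by at most one from the stratified target.
#'
#' @param ids Sample identifiers (unique).
#' @param labels Binary 0/1 labels aligned with `ids`.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return A tibble (`id`, `label`, `fold`) with `fold` in `1..k`.
#' @export
stratified_kfold <- function(ids, labels, k = 10L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(ids) != length(labels)) abort("ids and labels differ in length")
  if (anyDuplicated(ids)) abort("ids must be unique")
  if (k > length(ids)) abort("k exceeds the number of samples")
  if (length(unique(labels)) < 2L) abort("both classes must be present")
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  fold <- integer(length(ids))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  tibble(id = ids, label = labels, fold = fold)
}

#' Cross-validate the full feature-to-classifier pipeline
#'
#' Runs stratified k-fold cross-validation of the complete pipeline on an
#' extracted feature table: within each fold, the PCA reducer is fitted on
#' the training folds only (no leakage into the held-out fold; set
#' `pca_scope = "global"` to fit once on everything), the classifier is
#' trained, and the held-out fold is scored. Per-fold confusion counts,
#' metric bundles, ROC points and AUC are collected.
#'
#' @param data Feature tibble with an id column, a label column and
#'   feature columns (see [extract_features()]).
#' @param classifier `"dcnn"` for the convolutional network or a baseline
#'   kind (`"svm"`, `"nb"`, `"rf"`, `"ann"`).
#' @param k Number of folds (default 10).
#' @param d_out PCA output dimension (default 80); `NULL` skips reduction.
#' @param pca_scope `"fold"` (fit reducer per training split, default) or
#'   `"global"`.
#' @param seed Master seed; fold shuffling and model initialization draw
#'   from it.
#' @param id_col,label_col Column names (defaults `"id"`, `"label"`).
#' @param model_config,train Optional [default_dcnn()] /
#'   [train_config()] overrides for `classifier = "dcnn"`.
#' @param model_seed Seed stream for model initialization; defaults to
#'   `seed`. Varying it while holding `seed` fixed retrains on identical
#'   fold assignments, as the stable-misclassification analysis requires.
#' @param ... Extra arguments passed to [train_baseline()].
#' @return An `rtcp_cv` object; see [tidy.rtcp_cv()] for per-fold metrics
#'   and [glance.rtcp_cv()] for the mean bundle and pooled AUC.
#' @export
cross_validate <- function(data, classifier = c("dcnn", "svm", "nb", "rf", "ann"),
                           k = 10L, d_out = 80L,
                           pca_scope = c("fold", "global"), seed = 1L,
                           id_col = "id", label_col = "label",
                           model_config = NULL, train = NULL,
                           model_seed = seed, ...) {
  classifier <- match.arg(classifier)
  pca_scope <- match.arg(pca_scope)
  stopifnot(is.data.frame(data), id_col %in% names(data),
            label_col %in% names(data))
  ids <- data[[id_col]]
  y <- as.integer(data[[label_col]])
  folds <- stratified_kfold(ids, y, k = k, seed = seed)
  fold_of <- folds$fold[match(ids, folds$id)]
  X_all <- as_feature_matrix(data)
  if (!is.null(d_out) && pca_scope == "global") {
    X_all <- apply_reducer(fit_reducer(X_all, d_out), X_all)
  }

  fold_results <- purrr::map(seq_len(k), function(f) {
    tr <- fold_of != f; te <- !tr
    Xtr <- X_all[tr, , drop = FALSE]; Xte <- X_all[te, , drop = FALSE]
    if (!is.null(d_out) && pca_scope == "fold") {
      red <- fit_reducer(Xtr, d_out)
      Xtr <- apply_reducer(red, Xtr)
      Xte <- apply_reducer(red, Xte)
    }
    fold_seed <- (model_seed * 1009L + f) %% .Machine$integer.max
    model <- fit_classifier(Xtr, y[tr], classifier, fold_seed,
                            model_config = model_config, train = train, ...)
    scores <- predict_proba(model, Xte)
    pred <- as.integer(scores >= 0.5)
    cm <- confusion(y[te], pred)
    pts <- roc_points(scores, y[te])
    list(metrics = dplyr::mutate(metrics(cm), fold = f, .before = 1),
         confusion = cm, roc = dplyr::mutate(pts, fold = f, .before = 1),
         auc = auc(pts),
         scores = tibble(fold = f, id = ids[te], label = y[te],
                         score = scores, pred = pred))
  })

  structure(list(k = k, classifier = classifier, seed = seed,
                 d_out = d_out, pca_scope = pca_scope,
                 folds = folds,
                 fold_metrics = purrr::map_dfr(fold_results, "metrics"),
                 fold_auc = purrr::map_dbl(fold_results, "auc"),
                 roc = purrr::map_dfr(fold_results, "roc"),
                 predictions = purrr::map_dfr(fold_results, "scores")),
            class = "rtcp_cv")
}

fit_classifier <- function(X, y, classifier, seed, model_config = NULL,
                           train = NULL, ...) {
  if (classifier == "dcnn") {
    if (is.null(model_config)) model_config <- default_dcnn(ncol(X))
    if (is.null(train)) train <- train_config(epochs = 100L, seed = seed)
    else { train$seed <- as.integer(seed) }
    train_dcnn(X, y, config = model_config, train = train)
  } else {
    train_baseline(X, y, kind = classifier, seed = seed, ...)
  }
}

#' @export
print.rtcp_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<%d-fold CV of %s (pca %s, d=%s, seed %d)>\n", x$k,
              x$classifier, x$pca_scope,
              if (is.null(x$d_out)) "none" else x$d_out, x$seed))
  cat(sprintf("  acc %.4f  spec %.4f  sens %.4f  F %.4f  mcc %.4f  auc %.4f\n",
              g$acc, g$spec, g$sens, g$f_score, g$mcc, g$auc))
  invisible(x)
}

#' Per-fold and summary views of a cross-validation report
#'
#' `tidy()` returns one row per fold with the metric bundle and fold AUC;
#' `glance()` the across-fold mean of each metric together with the pooled
#' confusion accuracy.
#'
#' @param x An `rtcp_cv` object.
#' @param ... Unused.
#' @export
#' @method tidy rtcp_cv
tidy.rtcp_cv <- function(x, ...) {
  dplyr::mutate(x$fold_metrics, auc = x$fold_auc)
}

#' @rdname tidy.rtcp_cv
#' @export
#' @method glance rtcp_cv
glance.rtcp_cv <- function(x, ...) {
  m <- dplyr::summarise(x$fold_metrics, dplyr::across(
    c("acc", "spec", "sens", "pre", "f_score", "mcc"), mean))
  dplyr::mutate(m, auc = mean(x$fold_auc), k = x$k,
                classifier = x$classifier)
}

#' Stably misclassified samples under repeated training
#'
#' Repeats cross-validated training `n_models` times on fixed fold
#' assignments, re-seeding model initialization each repeat, and flags
#' samples whose misprediction count strictly exceeds `threshold`:
#' stable false positives (true negatives predicted positive) and stable
#' false negatives. The two id sets are disjoint by construction.
#'
#' @inheritParams cross_validate
#' @param n_models Number of independently seeded trainings.
#' @param threshold Misprediction count that must be strictly exceeded
#'   (default `n_models / 2`).
#' @return A list: `stable_fp`, `stable_fn` (character id vectors), and
#'   `counts`, a tibble (`id`, `label`, `n_wrong`).
#' @export
stable_misclassifications <- function(data, classifier = "svm",
                                      n_models = 100L, threshold = n_models / 2,
                                      k = 10L, d_out = 80L, seed = 1L,
                                      id_col = "id", label_col = "label", ...) {
  stopifnot(n_models >= 1L, threshold >= 0, threshold <= n_models)
  runs <- purrr::map(seq_len(n_models), function(r) {
    cv <- cross_validate(data, classifier = classifier, k = k, d_out = d_out,
                         seed = seed, model_seed = seed + r * 131L,
                         id_col = id_col, label_col = label_col, ...)
    dplyr::mutate(cv$predictions, wrong = .data$pred != .data$label)
  })
  counts <- dplyr::bind_rows(runs) |>
    dplyr::group_by(.data$id, .data$label) |>
    dplyr::summarise(n_wrong = sum(.data$wrong), .groups = "drop")
  list(stable_fp = counts$id[counts$label == 0L & counts$n_wrong > threshold],
       stable_fn = counts$id[counts$label == 1L & counts$n_wrong > threshold],
       counts = counts)
}
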