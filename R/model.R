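#' Valid-convolution output length
#'
#' Number of windows a filter of length `F` sliding with stride `S` fits in
#' an input of length `L` without padding: `floor((L - F) / S) + 1`.
#'
#' @param L Input length (`L >= F`).
#' @param F Filter length (`>= 1`).
#' @param S Stride (`>= 1`).
#' @return Integer window count.
#' @export
#' @examples
#' conv_output_length(80, 3, 2)  # 39
conv_output_length <- function(L, F, S) {
  stopifnot(F >= 1, S >= 1)
  if (L < F) abort(sprintf("input length %d shorter than filter length %d", L, F))
  as.integer((L - F) %/% S) + 1L
}

# "same"-padded output length (TensorFlow convention): ceil(L / S).
same_output_length <- function(L, S) as.integer(ceiling(L / S))

#' Network architecture presets
#'
#' `default_dcnn()` is the selected architecture: 5 convolutional layers of
#' 32 filters each, batch normalization after every convolution, max-pool
#' layers after the 2nd and 4th convolutions, and 2 fully connected layers
#' ending in a single sigmoid unit. Convolution and pooling strides are 2;
#' hidden activations are ReLU. `small_dcnn()` is the compact variant for
#' smaller datasets: 4 convolutions with 16, 16, 32 and 32 filters and
#' fully connected layers of 13 and 2 units under a softmax head.
#'
#' Convolutions and pools use "same" zero-padding, so each stride-2 stage
#' halves the length (rounding up); five convolutions plus two pools then
#' fit an 80-long input. Kernel size, pool placement and hidden width are
#' configurable.
#'
#' @param input_dim Length of the input feature vector (`>= 8`).
#' @param kernel_size Convolution filter length (default 3).
#' @param filters Integer vector, one filter count per conv layer.
#' @param pool_positions Conv-layer indices followed by a max-pool.
#' @param fc_sizes Fully connected widths; the last entry is the head
#'   (1 for sigmoid, 2 for softmax).
#' @param head `"sigmoid1"` or `"softmax2"`.
#' @return An `rtcp_model_config` list.
#' @export
#' @examples
#' default_dcnn(80)$filters
default_dcnn <- function(input_dim, kernel_size = 3L,
                         filters = rep(32L, 5L),
                         pool_positions = c(2L, 4L),
                         fc_sizes = c(64L, 1L),
                         head = "sigmoid1") {
  model_config(input_dim, filters, kernel_size, pool_positions, fc_sizes, head)
}

#' @rdname default_dcnn
#' @export
small_dcnn <- function(input_dim, kernel_size = 3L,
                       filters = c(16L, 16L, 32L, 32L),
                       pool_positions = c(2L, 4L),
                       fc_sizes = c(13L, 2L),
                       head = "softmax2") {
  model_config(input_dim, filters, kernel_size, pool_positions, fc_sizes, head)
}

model_config <- function(input_dim, filters, kernel_size, pool_positions,
                         fc_sizes, head) {
  input_dim <- as.integer(input_dim)
  if (input_dim < 8L) abort("input_dim must be >= 8")
  if (input_dim < kernel_size) abort("input_dim must be >= kernel_size")
  head <- match.arg(head, c("sigmoid1", "softmax2"))
  n_conv <- length(filters)
  if (!all(pool_positions %in% seq_len(n_conv))) {
    abort("pool_positions must be conv-layer indices")
  }
  n_out <- if (head == "sigmoid1") 1L else 2L
  fc_sizes <- as.integer(fc_sizes)
  if (fc_sizes[length(fc_sizes)] != n_out) {
    abort(sprintf("last fc size must be %d for head '%s'", n_out, head))
  }
  structure(list(n_conv = n_conv, filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size), conv_stride = 2L,
                 pool_positions = as.integer(pool_positions),
                 pool_size = 2L, pool_stride = 2L,
                 fc_sizes = fc_sizes, head = head,
                 input_dim = input_dim, padding = "same"),
            class = "rtcp_model_config")
}

#' @export
print.rtcp_model_config <- function(x, ...) {
  cat(sprintf("<dcnn config: %d conv layers [%s], kernel %d, pools after {%s}, fc [%s], %s head, input %d>\n",
              x$n_conv, paste(x$filters, collapse = ","), x$kernel_size,
              paste(x$pool_positions, collapse = ","),
              paste(x$fc_sizes, collapse = ","), x$head, x$input_dim))
  invisible(x)
}

#' Training schedule
#'
#' Adam optimisation of the binary cross-entropy (sigmoid head) or
#' cross-entropy (softmax head) loss under a step-decay learning-rate
#' schedule: the rate starts at `lr0` and is multiplied by
#' `lr_decay_factor` every `lr_decay_every` epochs. Defaults follow the
#' published schedule (1e-3, one-tenth every 100 epochs, 1000 epochs).
#'
#' @param epochs Number of training epochs (`>= 1`).
#' @param lr0 Initial learning rate.
#' @param lr_decay_factor Multiplicative decay in (0, 1].
#' @param lr_decay_every Epoch period of the decay steps.
#' @param batch_size Minibatch size.
#' @param seed Integer seed for initialization and shuffling.
#' @param validation_split Fraction of rows held out for per-epoch
#'   validation curves (0 disables).
#' @return An `rtcp_train_config` list.
#' @export
train_config <- function(epochs = 1000L, lr0 = 1e-3, lr_decay_factor = 0.1,
                         lr_decay_every = 100L, batch_size = 32L, seed = 1L,
                         validation_split = 0) {
  if (epochs < 1L) abort("epochs must be >= 1")
  if (lr_decay_factor <= 0 || lr_decay_factor > 1) {
    abort("lr_decay_factor must be in (0, 1]")
  }
  structure(list(epochs = as.integer(epochs), lr0 = lr0,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 validation_split = validation_split,
                 loss = "binary cross-entropy", optimizer = "adam"),
            class = "rtcp_train_config")
}

#' @rdname train_config
#' @param tc An `rtcp_train_config`.
#' @param epoch 0-based epoch index (vectorised).
#' @return `learning_rate_at()` returns the scheduled rate(s).
#' @export
#' @examples
#' learning_rate_at(train_config(), c(0, 100, 250))  # 1e-3 1e-4 1e-5
learning_rate_at <- function(tc, epoch) {
  tc$lr0 * tc$lr_decay_factor^(epoch %/% tc$lr_decay_every)
}

## ---- layer primitives (n x L x C arrays, column-major im2col) ----

pad_same <- function(L, F, S) {
  L_out <- same_output_length(L, S)
  total <- max((L_out - 1L) * S + F - L, 0L)
  c(left = total %/% 2L, right = total - total %/% 2L, L_out = L_out)
}

conv1d_forward <- function(A, W, b, S, pad) {
  d <- dim(A); n <- d[1]; L <- d[2]; Cin <- d[3]
  F <- nrow(W) / Cin
  pl <- pad[["left"]]; pr <- pad[["right"]]; L_out <- pad[["L_out"]]
  Ap <- array(0, c(n, L + pl + pr, Cin))
  Ap[, pl + seq_len(L), ] <- A
  cols <- array(0, c(n, L_out, F, Cin))
  base <- (seq_len(L_out) - 1L) * S
  for (f in seq_len(F)) cols[, , f, ] <- Ap[, base + f, , drop = FALSE]
  dim(cols) <- c(n * L_out, F * Cin)
  Y <- cols %*% W
  Y <- sweep(Y, 2, b, "+")
  dim(Y) <- c(n, L_out, ncol(W))
  list(out = Y, cols = cols, dims = c(n = n, L = L, Cin = Cin, F = F,
                                      L_out = L_out, pl = pl, pr = pr, S = S))
}

conv1d_backward <- function(dY, W, cache) {
  d <- cache$dims
  n <- d[["n"]]; L <- d[["L"]]; Cin <- d[["Cin"]]; F <- d[["F"]]
  L_out <- d[["L_out"]]; pl <- d[["pl"]]; pr <- d[["pr"]]; S <- d[["S"]]
  Cout <- ncol(W)
  dY2 <- dY; dim(dY2) <- c(n * L_out, Cout)
  dW <- crossprod(cache$cols, dY2)
  db <- colSums(dY2)
  dcols <- dY2 %*% t(W)
  dim(dcols) <- c(n, L_out, F, Cin)
  dAp <- array(0, c(n, L + pl + pr, Cin))
  base <- (seq_len(L_out) - 1L) * S
  for (f in seq_len(F)) {
    idx <- base + f
    dc <- dcols[, , f, , drop = FALSE]
    dim(dc) <- c(n, L_out, Cin)
    cur <- dAp[, idx, , drop = FALSE]
    dim(cur) <- c(n, L_out, Cin)
    dAp[, idx, ] <- cur + dc
  }
  list(dA = dAp[, pl + seq_len(L), , drop = FALSE], dW = dW, db = db)
}

bn_forward <- function(A, gamma, beta, run_mean, run_var, train,
                       momentum = 0.9, eps = 1e-5) {
  d <- dim(A); n <- d[1]; L <- d[2]; C <- d[3]
  m <- n * L
  X <- A; dim(X) <- c(m, C)
  if (train) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2, mu)^2)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
  }
  xhat <- sweep(sweep(X, 2, mu), 2, sqrt(v + eps), "/")
  Y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  dim(Y) <- d
  list(out = Y, xhat = xhat, var = v, eps = eps, dims = d,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dY, gamma, cache) {
  d <- cache$dims
  m <- d[1] * d[2]; C <- d[3]
  dY2 <- dY; dim(dY2) <- c(m, C)
  xhat <- cache$xhat
  dgamma <- colSums(dY2 * xhat)
  dbeta <- colSums(dY2)
  dxhat <- sweep(dY2, 2, gamma, "*")
  inv_sd <- 1 / sqrt(cache$var + cache$eps)
  dX <- sweep(m * dxhat, 2, colSums(dxhat), "-") -
    sweep(xhat, 2, colSums(dxhat * xhat), "*")
  dX <- sweep(dX, 2, inv_sd / m, "*")
  dim(dX) <- d
  list(dA = dX, dgamma = dgamma, dbeta = dbeta)
}

maxpool2_forward <- function(A) {
  d <- dim(A); n <- d[1]; L <- d[2]; C <- d[3]
  L_out <- same_output_length(L, 2L)
  Ap <- array(-Inf, c(n, 2L * L_out, C))
  Ap[, seq_len(L), ] <- A
  A1 <- Ap[, seq(1L, 2L * L_out, 2L), , drop = FALSE]
  A2 <- Ap[, seq(2L, 2L * L_out, 2L), , drop = FALSE]
  mask <- A1 >= A2          # ties go to the earlier position
  Y <- pmax(A1, A2)
  list(out = Y, mask = mask, L = L, dims_out = c(n, L_out, C))
}

maxpool2_backward <- function(dY, cache) {
  n <- cache$dims_out[1]; L_out <- cache$dims_out[2]; C <- cache$dims_out[3]
  dAp <- array(0, c(n, 2L * L_out, C))
  dAp[, seq(1L, 2L * L_out, 2L), ] <- dY * cache$mask
  dAp[, seq(2L, 2L * L_out, 2L), ] <- dY * !cache$mask
  dAp[, seq_len(cache$L), , drop = FALSE]
}

## ---- parameter construction and full forward/backward ----

init_params <- function(mc) {
  params <- list()
  L <- mc$input_dim; Cin <- 1L
  for (i in seq_len(mc$n_conv)) {
    Cout <- mc$filters[i]
    fan_in <- mc$kernel_size * Cin
    params[[paste0("conv", i, "_W")]] <-
      matrix(stats::rnorm(fan_in * Cout, sd = sqrt(2 / fan_in)), fan_in, Cout)
    params[[paste0("conv", i, "_b")]] <- numeric(Cout)
    params[[paste0("bn", i, "_gamma")]] <- rep(1, Cout)
    params[[paste0("bn", i, "_beta")]] <- numeric(Cout)
    L <- same_output_length(L, mc$conv_stride)
    Cin <- Cout
    if (i %in% mc$pool_positions) L <- same_output_length(L, mc$pool_stride)
  }
  width <- L * Cin
  for (j in seq_along(mc$fc_sizes)) {
    out_w <- mc$fc_sizes[j]
    params[[paste0("fc", j, "_W")]] <-
      matrix(stats::rnorm(width * out_w, sd = sqrt(2 / width)), width, out_w)
    params[[paste0("fc", j, "_b")]] <- numeric(out_w)
    width <- out_w
  }
  params
}

# Running batch-norm statistics, kept outside the trainable parameters.
init_bn_state <- function(mc) {
  st <- list()
  for (i in seq_len(mc$n_conv)) {
    st[[paste0("bn", i, "_mean")]] <- numeric(mc$filters[i])
    st[[paste0("bn", i, "_var")]] <- rep(1, mc$filters[i])
  }
  st
}

dcnn_forward <- function(mc, params, bn_state, X, train = FALSE) {
  n <- nrow(X)
  A <- array(X, c(n, ncol(X), 1L))
  caches <- list()
  for (i in seq_len(mc$n_conv)) {
    pad <- pad_same(dim(A)[2], mc$kernel_size, mc$conv_stride)
    cv <- conv1d_forward(A, params[[paste0("conv", i, "_W")]],
                         params[[paste0("conv", i, "_b")]], mc$conv_stride, pad)
    bn <- bn_forward(cv$out, params[[paste0("bn", i, "_gamma")]],
                     params[[paste0("bn", i, "_beta")]],
                     bn_state[[paste0("bn", i, "_mean")]],
                     bn_state[[paste0("bn", i, "_var")]], train)
    if (train) {
      bn_state[[paste0("bn", i, "_mean")]] <- bn$run_mean
      bn_state[[paste0("bn", i, "_var")]] <- bn$run_var
    }
    A2 <- bn$out
    relu_mask <- A2 > 0
    A2[!relu_mask] <- 0
    pool <- NULL
    if (i %in% mc$pool_positions) {
      pool <- maxpool2_forward(A2)
      A2 <- pool$out
    }
    caches[[i]] <- list(conv = cv, bn = bn, relu = relu_mask, pool = pool)
    A <- A2
  }
  flat_dim <- dim(A)
  Z <- A; dim(Z) <- c(n, prod(flat_dim[2:3]))
  fc_caches <- list()
  n_fc <- length(mc$fc_sizes)
  for (j in seq_len(n_fc)) {
    W <- params[[paste0("fc", j, "_W")]]
    out <- sweep(Z %*% W, 2, params[[paste0("fc", j, "_b")]], "+")
    if (j < n_fc) {
      relu_mask <- out > 0
      act <- out; act[!relu_mask] <- 0
      fc_caches[[j]] <- list(input = Z, relu = relu_mask)
      Z <- act
    } else {
      fc_caches[[j]] <- list(input = Z, relu = NULL)
      Z <- out
    }
  }
  probs <- if (mc$head == "sigmoid1") {
    1 / (1 + exp(-Z[, 1]))
  } else {
    e <- exp(Z - apply(Z, 1, max))
    (e / rowSums(e))[, 2]          # probability of class 1
  }
  list(logits = Z, probs = probs, caches = caches, fc_caches = fc_caches,
       flat_dim = flat_dim, bn_state = bn_state)
}

dcnn_backward <- function(mc, params, fw, y) {
  n <- length(y)
  # gradient of mean cross-entropy wrt logits
  if (mc$head == "sigmoid1") {
    dZ <- matrix((fw$probs - y) / n, ncol = 1L)
  } else {
    P <- cbind(1 - fw$probs, fw$probs)
    Y <- cbind(1 - y, y)
    dZ <- (P - Y) / n
  }
  grads <- list()
  n_fc <- length(mc$fc_sizes)
  for (j in rev(seq_len(n_fc))) {
    cc <- fw$fc_caches[[j]]
    grads[[paste0("fc", j, "_W")]] <- crossprod(cc$input, dZ)
    grads[[paste0("fc", j, "_b")]] <- colSums(dZ)
    dZ_in <- dZ %*% t(params[[paste0("fc", j, "_W")]])
    if (j > 1L) dZ_in <- dZ_in * fw$fc_caches[[j - 1L]]$relu
    dZ <- dZ_in
  }
  dA <- dZ
  dim(dA) <- fw$flat_dim
  for (i in rev(seq_len(mc$n_conv))) {
    cc <- fw$caches[[i]]
    if (!is.null(cc$pool)) dA <- maxpool2_backward(dA, cc$pool)
    dA <- dA * cc$relu
    bn <- bn_backward(dA, params[[paste0("bn", i, "_gamma")]], cc$bn)
    grads[[paste0("bn", i, "_gamma")]] <- bn$dgamma
    grads[[paste0("bn", i, "_beta")]] <- bn$dbeta
    cv <- conv1d_backward(bn$dA, params[[paste0("conv", i, "_W")]], cc$conv)
    grads[[paste0("conv", i, "_W")]] <- cv$dW
    grads[[paste0("conv", i, "_b")]] <- cv$db
    dA <- cv$dA
  }
  grads
}

cross_entropy_loss <- function(probs, y, eps = 1e-12) {
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the convolutional classifier
#'
#' Fits the 1-D convolutional network by minibatch Adam on the
#' cross-entropy loss, with the step-decay learning-rate schedule of
#' [train_config()]. Training is deterministic for a fixed seed in
#' single-threaded BLAS mode.
#'
#' @param data Feature tibble (see [extract_features()] /
#'   [apply_reducer()]) or numeric matrix of shape n x input_dim.
#' @param labels Binary 0/1 vector, or the name of a label column in
#'   `data` (default `"label"` if present).
#' @param config An `rtcp_model_config`; default [default_dcnn()] sized to
#'   the data.
#' @param train An `rtcp_train_config`.
#' @return An `rtcp_dcnn` object: configs, fitted parameters, batch-norm
#'   state, and a per-epoch `history` tibble (epoch, lr, train_loss,
#'   train_acc, val_loss, val_acc).
#' @export
train_dcnn <- function(data, labels = NULL, config = NULL,
                       train = train_config(epochs = 100L)) {
  xy <- resolve_xy(data, labels)
  X <- xy$X; y <- xy$y
  if (is.null(config)) config <- default_dcnn(ncol(X))
  if (ncol(X) != config$input_dim) {
    abort(sprintf("data has %d feature columns but config expects %d",
                  ncol(X), config$input_dim))
  }
  tc <- train
  old_seed <- local_seed(tc$seed)
  on.exit(restore_seed(old_seed), add = TRUE)

  val_idx <- integer(0)
  if (tc$validation_split > 0) {
    val_idx <- sample(nrow(X), size = floor(tc$validation_split * nrow(X)))
  }
  tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]

  params <- init_params(config)
  bn_state <- init_bn_state(config)
  m_adam <- lapply(params, function(p) p * 0)
  v_adam <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  hist <- vector("list", tc$epochs)

  for (epoch in seq_len(tc$epochs) - 1L) {
    lr <- learning_rate_at(tc, epoch)
    ord <- sample(length(ytr))
    batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    ep_loss <- 0; ep_correct <- 0
    for (b in batches) {
      fw <- dcnn_forward(config, params, bn_state, Xtr[b, , drop = FALSE],
                         train = TRUE)
      bn_state <- fw$bn_state
      grads <- dcnn_backward(config, params, fw, ytr[b])
      step <- step + 1L
      for (nm in names(params)) {
        g <- grads[[nm]]
        m_adam[[nm]] <- beta1 * m_adam[[nm]] + (1 - beta1) * g
        v_adam[[nm]] <- beta2 * v_adam[[nm]] + (1 - beta2) * g^2
        mhat <- m_adam[[nm]] / (1 - beta1^step)
        vhat <- v_adam[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      ep_loss <- ep_loss + cross_entropy_loss(fw$probs, ytr[b]) * length(b)
      ep_correct <- ep_correct + sum((fw$probs >= 0.5) == (ytr[b] == 1))
    }
    val_loss <- NA_real_; val_acc <- NA_real_
    if (length(val_idx) > 0L) {
      fv <- dcnn_forward(config, params, bn_state, X[val_idx, , drop = FALSE])
      val_loss <- cross_entropy_loss(fv$probs, y[val_idx])
      val_acc <- mean((fv$probs >= 0.5) == (y[val_idx] == 1))
    }
    hist[[epoch + 1L]] <- tibble(
      epoch = epoch, lr = lr,
      train_loss = ep_loss / length(ytr),
      train_acc = ep_correct / length(ytr),
      val_loss = val_loss, val_acc = val_acc)
  }
  structure(list(config = config, train_config = tc, params = params,
                 bn_state = bn_state, history = dplyr::bind_rows(hist)),
            class = "rtcp_dcnn")
}

#' @export
print.rtcp_dcnn <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf("<dcnn: %d epochs trained, final train acc %.3f, loss %.4f>\n",
              nrow(x$history), h$train_acc, h$train_loss))
  print(x$config)
  invisible(x)
}

#' @export
#' @method tidy rtcp_dcnn
tidy.rtcp_dcnn <- function(x, ...) x$history

#' @export
#' @method glance rtcp_dcnn
glance.rtcp_dcnn <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble(epochs = nrow(x$history), final_lr = h$lr,
         train_loss = h$train_loss, train_acc = h$train_acc,
         val_loss = h$val_loss, val_acc = h$val_acc,
         n_parameters = sum(vapply(x$params, length, integer(1))))
}

#' Predict class probabilities or labels
#'
#' @param object A fitted `rtcp_dcnn` or `rtcp_baseline`.
#' @param data Feature tibble or matrix with the width the model was
#'   trained on.
#' @param ... Unused.
#' @return `predict_proba()` gives the probability of the positive class
#'   (label 1); `predict_label()` thresholds it (sigmoid head) or takes the
#'   larger of the two class scores (softmax head; equivalent at 0.5).
#' @export
predict_proba <- function(object, data, ...) UseMethod("predict_proba")

#' @export
#' @method predict_proba rtcp_dcnn
predict_proba.rtcp_dcnn <- function(object, data, ...) {
  X <- as_feature_matrix(data)
  if (ncol(X) != object$config$input_dim) {
    abort(sprintf("model expects %d feature columns, got %d",
                  object$config$input_dim, ncol(X)))
  }
  dcnn_forward(object$config, object$params, object$bn_state, X)$probs
}

#' @rdname predict_proba
#' @param threshold Probability cutoff for the positive label.
#' @export
predict_label <- function(object, data, threshold = 0.5, ...) {
  as.integer(predict_proba(object, data, ...) >= threshold)
}

## ---- conventional baselines ----

#' Fit a conventional baseline classifier
#'
#' Wraps the standard fits used for comparison with the convolutional
#' network behind one contract: an RBF-kernel support vector machine with
#' penalty 1e5 and gamma `1/p` ("auto"), naive Bayes, random forest, and a
#' single-hidden-layer feed-forward network. All expose
#' [predict_proba()]-style positive-class scores for ROC analysis.
#'
#' @param data Feature tibble or matrix.
#' @param labels Binary 0/1 vector or label column name.
#' @param kind One of `"svm"`, `"nb"`, `"rf"`, `"ann"`.
#' @param ... Overrides passed to the underlying fit (e.g. `ntree` for
#'   `"rf"`, `size` for `"ann"`, `cost`/`gamma` for `"svm"`).
#' @param seed Integer seed for the stochastic fits.
#' @return An `rtcp_baseline` object.
#' @export
train_baseline <- function(data, labels = NULL,
                           kind = c("svm", "nb", "rf", "ann"), ...,
                           seed = 1L) {
  kind <- match.arg(kind)
  xy <- resolve_xy(data, labels)
  X <- xy$X; yf <- factor(xy$y, levels = c(0, 1))
  dots <- list(...)
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  fit <- switch(kind,
    svm = {
      args <- utils::modifyList(
        list(x = X, y = yf, kernel = "radial", cost = 1e5,
             gamma = 1 / ncol(X), scale = FALSE, probability = FALSE),
        dots)
      do.call(e1071::svm, args)
    },
    nb = {
      # call directly: naiveBayes deparses its y argument for labelling,
      # which do.call-style construction would inline as the whole factor
      nb_df <- as.data.frame(X)
      e1071::naiveBayes(x = nb_df, y = yf, laplace = dots$laplace %||% 0)
    },
    rf = do.call(randomForest::randomForest,
                 utils::modifyList(list(x = X, y = yf, ntree = 200L), dots)),
    ann = {
      args <- utils::modifyList(
        list(x = X, y = as.numeric(xy$y), size = 16L, decay = 1e-4,
             maxit = 200L, entropy = TRUE, trace = FALSE,
             MaxNWts = 1e5), dots)
      do.call(nnet::nnet, args)
    })
  structure(list(kind = kind, fit = fit, p = ncol(X)),
            class = "rtcp_baseline")
}

#' @export
print.rtcp_baseline <- function(x, ...) {
  cat(sprintf("<baseline classifier: %s, %d features>\n", x$kind, x$p))
  invisible(x)
}

#' @export
#' @method predict_proba rtcp_baseline
predict_proba.rtcp_baseline <- function(object, data, ...) {
  X <- as_feature_matrix(data)
  if (ncol(X) != object$p) {
    abort(sprintf("model expects %d feature columns, got %d", object$p, ncol(X)))
  }
  switch(object$kind,
    svm = {
      pred <- stats::predict(object$fit, X, decision.values = TRUE)
      dv <- drop(attr(pred, "decision.values"))
      # e1071 names the column "A/B" with positive values favouring A;
      # orient so larger = class "1", then squash to (0,1)
      if (grepl("^0/", colnames(attr(pred, "decision.values"))[1])) dv <- -dv
      1 / (1 + exp(-dv))
    },
    nb = stats::predict(object$fit, as.data.frame(X), type = "raw")[, "1"],
    rf = stats::predict(object$fit, X, type = "prob")[, "1"],
    ann = drop(stats::predict(object$fit, X)))
}

## ---- shared helpers ----

# Resolve (data, labels) into a numeric matrix + 0/1 vector.
resolve_xy <- function(data, labels) {
  if (is.null(labels) && is.data.frame(data) && "label" %in% names(data)) {
    labels <- "label"
  }
  if (is.character(labels) && length(labels) == 1L && is.data.frame(data)) {
    y <- data[[labels]]
  } else {
    y <- labels
  }
  if (is.null(y)) abort("no labels supplied and no `label` column found")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) abort("labels must be binary 0/1")
  X <- as_feature_matrix(data)
  if (nrow(X) != length(y)) abort("row count of data does not match labels")
  list(X = X, y = y)
}

# Seed scoping that restores the caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
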