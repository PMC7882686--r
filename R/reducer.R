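#' Fit a PCA reducer on a feature matrix
#'
#' Principal-component compression of the composite RTCP feature before
#' classification; the default keeps 80 components. Components are the top
#' eigenvectors of the covariance of the centred training data, with sign
#' fixed so each component's largest-magnitude loading is positive, making
#' the projection deterministic.
#'
#' @param data A data frame containing feature columns (see
#'   [feature_columns()]) or a numeric matrix (rows = proteins).
#' @param d_out Output dimension; must satisfy
#'   `d_out <= min(nrow - 1, ncol)`.
#' @return An `rtcp_reducer`: `mean` (column means), `components`
#'   (`d_out` x p orthonormal rows), `d_out`, `sdev` (component standard
#'   deviations) and `schema` (input column names).
#' @export
#' @examples
#' X <- matrix(rnorm(200), 20, 10)
#' r <- fit_reducer(X, d_out = 3)
#' dim(apply_reducer(r, X))
fit_reducer <- function(data, d_out = 80L) {
  X <- as_feature_matrix(data)
  n <- nrow(X); p <- ncol(X)
  d_out <- as.integer(d_out)
  if (d_out < 1L) abort("d_out must be >= 1")
  if (d_out > min(n - 1L, p)) {
    abort(sprintf("d_out = %d exceeds min(n_samples - 1, n_features) = %d",
                  d_out, min(n - 1L, p)))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = d_out)
  comp <- t(pc$rotation[, seq_len(d_out), drop = FALSE])  # d_out x p
  # deterministic sign: largest |loading| positive
  for (i in seq_len(d_out)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  structure(list(mean = pc$center, components = comp, d_out = d_out,
                 sdev = pc$sdev[seq_len(d_out)], schema = colnames(X),
                 total_var = sum(pc$sdev^2)),
            class = "rtcp_reducer")
}

#' @rdname fit_reducer
#' @param reducer An `rtcp_reducer`.
#' @return `apply_reducer()` returns a tibble with columns `pc1..pcD` (plus
#'   any non-feature columns of `data` carried through) when `data` is a
#'   data frame, or a plain matrix when `data` is a matrix.
#' @export
apply_reducer <- function(reducer, data) {
  stopifnot(inherits(reducer, "rtcp_reducer"))
  X <- as_feature_matrix(data)
  if (ncol(X) != length(reducer$mean)) {
    abort(sprintf("reducer expects %d feature columns, got %d",
                  length(reducer$mean), ncol(X)))
  }
  Z <- sweep(X, 2, reducer$mean) %*% t(reducer$components)
  colnames(Z) <- paste0("pc", seq_len(reducer$d_out))
  if (is.data.frame(data)) {
    meta <- data[, setdiff(names(data), feature_columns(data)), drop = FALSE]
    dplyr::bind_cols(as_tibble(meta), as_tibble(Z))
  } else {
    Z
  }
}

# Accepts a feature tibble or a plain numeric matrix.
as_feature_matrix <- function(data) {
  if (is.matrix(data)) {
    storage.mode(data) <- "double"
    if (is.null(colnames(data))) colnames(data) <- paste0("f", seq_len(ncol(data)))
    return(data)
  }
  stopifnot(is.data.frame(data))
  cols <- feature_columns(data)
  if (length(cols) == 0L) abort("no feature columns found in `data`")
  as.matrix(data[, cols, drop = FALSE])
}

#' @export
print.rtcp_reducer <- function(x, ...) {
  cat(sprintf("<PCA reducer: %d -> %d dims, %.1f%% variance kept>\n",
              length(x$mean), x$d_out, 100 * sum(x$sdev^2) / x$total_var))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy rtcp_reducer
tidy.rtcp_reducer <- function(x, ...) {
  tibble(component = paste0("pc", seq_len(x$d_out)),
         sdev = x$sdev,
         var_explained = x$sdev^2 / x$total_var)
}

#' @export
#' @method glance rtcp_reducer
glance.rtcp_reducer <- function(x, ...) {
  tibble(input_dim = length(x$mean), d_out = x$d_out,
         var_retained = sum(x$sdev^2) / x$total_var)
}
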