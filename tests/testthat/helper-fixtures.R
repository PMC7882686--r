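# Shared fixtures, all generated in code.

# Two well-separated Gaussian clouds in feature space.
separable_features <- function(n_per_class = 100, p = 80, sep = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p, -sep / 2), n_per_class, p),
             matrix(rnorm(n_per_class * p, sep / 2), n_per_class, p))
  colnames(X) <- paste0("pc", seq_len(p))
  list(X = X, y = rep(c(0L, 1L), each = n_per_class))
}

random_pssm <- function(id = "p1", L = 10, seed = 1) {
  set.seed(seed)
  seq <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L,
                      replace = TRUE), collapse = "")
  new_pssm(id, seq, matrix(round(rnorm(L * 20, 0, 2)), L, 20))
}

random_aa_seq <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L, replace = TRUE),
        collapse = "")
}

# Independent brute-force oracle: count overlapping 3-windows in a named
# dictionary, then normalize.
brute_force_tripeptides <- function(reduced, K) {
  counts <- new.env()
  L <- length(reduced)
  for (i in seq_len(L - 2)) {
    key <- paste(reduced[i], reduced[i + 1], reduced[i + 2], sep = "-")
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  labels <- tripeptide_labels(K)
  v <- vapply(labels, function(k) (counts[[k]] %||% 0) / (L - 2), numeric(1))
  names(v) <- labels
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny network for structural tests.
tiny_dcnn <- function(input_dim = 12L) {
  rtcp:::model_config(input_dim, filters = c(3L, 4L), kernel_size = 3L,
                      pool_positions = 2L, fc_sizes = c(5L, 1L),
                      head = "sigmoid1")
}

# A small synthetic dataset extracted to features, memoised per options.
synth_features <- local({
  cache <- list()
  function(n_per_class = 100, signal = 0.5, shift = 1.0, seed = 7,
           length_range = c(50L, 150L)) {
    key <- paste(n_per_class, signal, shift, seed,
                 paste(length_range, collapse = "-"), sep = "|")
    if (is.null(cache[[key]])) {
      d <- generate_dataset(synthetic_spec(
        n_per_class = n_per_class, length_range = length_range,
        signal_strength = signal, pssm_shift = shift, seed = seed))
      cache[[key]] <<- extract_features(d$sequences, d$spec$alphabet, d$pssms)
    }
    cache[[key]]
  }
})
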