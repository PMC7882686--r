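#' Specify a synthetic two-class protein dataset
#'
#' Describes a labeled set of synthetic protein sequences and matching
#' PSSMs in which the two classes differ (a) in reduced-alphabet
#' tripeptide usage and (b) in PSSM score location. Class signal is
#' injected at the reduced-alphabet level: each class draws
#' reduced-symbol sequences from its own first-order Markov chain over the
#' alphabet classes, the two chains being a common uniform base transition
#' matrix perturbed multiplicatively by `1 +/- signal_strength` on a
#' seeded half of the entries (rows re-normalized) for class 1. Each
#' reduced symbol is then back-translated to a uniformly random amino acid
#' of that class, so the tripeptide composition is, by construction, a
#' sufficient feature. Synthetic PSSM scores are i.i.d. Normal(0, sd 2)
#' rounded to integers, with `pssm_shift` added to a seeded subset of 5 of
#' the 20 columns for class 1; they emulate only the statistical shape of
#' real log-odds profiles, not alignment structure.
#'
#' @param n_per_class Sequences per class (`>= 1`).
#' @param length_range Integer (min, max) sequence length, min `>= 3`.
#'   Default 50-400, the span of typical single-domain to medium
#'   multi-domain proteins.
#' @param alphabet Reduced alphabet the signal lives in (default canonical
#'   ST_SS).
#' @param signal_strength Perturbation size in `[0, 1]`; 0 makes the two
#'   classes identically distributed.
#' @param pssm_shift Additive mean shift of the class-1 PSSM columns.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An `rtcp_synth_spec` list.
#' @export
synthetic_spec <- function(n_per_class = 200L, length_range = c(50L, 400L),
                           alphabet = canonical_alphabets()$ST_SS,
                           signal_strength = 0.5, pssm_shift = 1.0,
                           seed = 1L) {
  length_range <- as.integer(length_range)
  if (n_per_class < 1L) abort("n_per_class must be >= 1")
  if (length(length_range) != 2L || length_range[1] < 3L ||
      length_range[2] < length_range[1]) {
    abort("length_range must be (min, max) with min >= 3")
  }
  if (signal_strength < 0 || signal_strength > 1) {
    abort("signal_strength must be in [0, 1]")
  }
  stopifnot(inherits(alphabet, "rtcp_alphabet"))
  structure(list(n_per_class = as.integer(n_per_class),
                 length_range = length_range, alphabet = alphabet,
                 signal_strength = signal_strength, pssm_shift = pssm_shift,
                 seed = as.integer(seed)),
            class = "rtcp_synth_spec")
}

#' Generate a synthetic labeled dataset
#'
#' Draws sequences and PSSMs per [synthetic_spec()]. Class 0 uses the base
#' (uniform) Markov chain and unshifted PSSM scores; class 1 the perturbed
#' chain and column-shifted scores.
#'
#' @param spec An `rtcp_synth_spec`.
#' @return A list with `sequences` (tibble: `id`, `seq`, `label`),
#'   `pssms` (named list of `rtcp_pssm` keyed by id) and `spec`.
#' @export
#' @examples
#' d <- generate_dataset(synthetic_spec(n_per_class = 3, seed = 42))
#' d$sequences
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "rtcp_synth_spec"))
  old_seed <- local_seed(spec$seed)
  on.exit(restore_seed(old_seed), add = TRUE)

  ab <- spec$alphabet
  K <- alphabet_size(ab)
  class_letters <- strsplit(ab$classes, "")

  base <- matrix(1 / K, K, K)
  # seeded half of the entries scaled up for class 1, the rest down
  sign_mask <- matrix(sample(c(1, -1), K * K, replace = TRUE), K, K)
  shifted <- base * (1 + spec$signal_strength * sign_mask)
  shifted <- shifted / rowSums(shifted)
  trans <- list(`0` = base, `1` = shifted)
  shift_cols <- sample(20L, 5L)

  n <- spec$n_per_class
  labels <- rep(c(0L, 1L), each = n)
  ids <- sprintf("synth_%04d", seq_along(labels))
  lens <- sample(seq(spec$length_range[1], spec$length_range[2]),
                 length(labels), replace = TRUE)

  seqs <- character(length(labels))
  pssms <- vector("list", length(labels))
  for (s in seq_along(labels)) {
    P <- trans[[as.character(labels[s])]]
    L <- lens[s]
    states <- integer(L)
    states[1] <- sample(K, 1L)
    for (t in 2:L) states[t] <- sample(K, 1L, prob = P[states[t - 1L], ])
    aa <- vapply(states, function(st) {
      cl <- class_letters[[st]]
      cl[sample(length(cl), 1L)]
    }, character(1))
    seqs[s] <- paste(aa, collapse = "")
    sc <- matrix(stats::rnorm(L * 20L, mean = 0, sd = 2), L, 20L)
    if (labels[s] == 1L) sc[, shift_cols] <- sc[, shift_cols] + spec$pssm_shift
    pssms[[s]] <- new_pssm(ids[s], seqs[s], round(sc))
  }
  names(pssms) <- ids
  list(sequences = tibble(id = ids, seq = seqs, label = labels),
       pssms = pssms, spec = spec)
}

#' Write a synthetic dataset to disk as plain-text fixtures
#'
#' Emits a FASTA file of the sequences, one PSI-BLAST-dialect ASCII PSSM
#' per protein (named `<id>.pssm`), a labels TSV (`id`, `label`) and a
#' JSON manifest recording the generating seed and a hash of the spec.
#' Everything round-trips losslessly through [read_fasta()] and
#' [parse_pssm_ascii()].
#'
#' @param dataset A list from [generate_dataset()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a tibble manifest of the files written.
#' @export
write_fixtures <- function(dataset, out_dir) {
  stopifnot(is.list(dataset), !is.null(dataset$sequences))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory '%s'", out_dir))

  fasta_path <- file.path(out_dir, "sequences.fasta")
  write_fasta(dataset$sequences, fasta_path)
  labels_path <- file.path(out_dir, "labels.tsv")
  utils::write.table(dataset$sequences[, c("id", "label")], labels_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pssm_paths <- purrr::imap_chr(dataset$pssms, function(p, id) {
    path <- file.path(out_dir, paste0(id, ".pssm"))
    write_pssm_ascii(p, path)
    path
  })
  spec <- dataset$spec
  spec_str <- paste(spec$n_per_class, spec$length_range[1],
                    spec$length_range[2], spec$alphabet$name,
                    paste(spec$alphabet$classes, collapse = "|"),
                    spec$signal_strength, spec$pssm_shift, sep = ";")
  manifest <- list(seed = spec$seed,
                   spec_hash = sprintf("%08x", digest32(spec_str)),
                   n_per_class = spec$n_per_class,
                   length_range = spec$length_range,
                   alphabet = spec$alphabet$name,
                   signal_strength = spec$signal_strength,
                   pssm_shift = spec$pssm_shift,
                   files = list(fasta = basename(fasta_path),
                                labels = basename(labels_path),
                                pssms = basename(unname(pssm_paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(tibble(file = c(fasta_path, labels_path, unname(pssm_paths),
                            file.path(out_dir, "manifest.json"))))
}

# Small stable polynomial hash; enough to fingerprint a spec in a manifest.
digest32 <- function(x) {
  h <- 17
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  h
}
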