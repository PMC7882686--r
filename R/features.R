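#' Sigmoid scaling of a substitution score
#'
#' Maps a signed log-odds score onto (0, 1) via `1 / (1 + exp(-a))`, the
#' scaling applied to every PSSM entry before position-averaging.
#'
#' @param a Numeric vector of finite scores.
#' @return Numeric vector in (0, 1).
#' @export
#' @examples
#' sigmoid_scale(0)       # 0.5
#' sigmoid_scale(log(3))  # 0.75
sigmoid_scale <- function(a) {
  stopifnot(is.numeric(a), all(is.finite(a)))
  1 / (1 + exp(-a))
}

#' 20-dimensional PSSM summary feature
#'
#' Sigmoid-scales every entry of the L x 20 score matrix and averages over
#' positions, giving one value per target amino acid: component j is
#' `mean_i 1/(1+exp(-a_ij))`. Invariant to the order of positions.
#'
#' @param pssm An `rtcp_pssm`.
#' @return Named numeric vector of length 20 (names `pssm_A` ... `pssm_Y`
#'   in PSI-BLAST column order), all entries strictly in (0, 1).
#' @export
#' @examples
#' p <- new_pssm("toy", "ACDEF", matrix(0, 5, 20))
#' pssm_feature(p)  # all 0.5
pssm_feature <- function(pssm) {
  stopifnot(inherits(pssm, "rtcp_pssm"))
  v <- colMeans(sigmoid_scale(pssm$scores))
  names(v) <- paste0("pssm_", PSSM_COLS)
  v
}

#' Tripeptide composition of a reduced-symbol sequence
#'
#' Counts the overlapping length-3 windows of the reduced sequence and
#' divides by the window count (L - 2), giving a probability vector over
#' the K^3 possible reduced tripeptides. Coordinates are ordered
#' lexicographically by (x, y, z) class index and labelled `"x-y-z"`.
#'
#' @param reduced Integer vector of 0-based class indices, length >= 3
#'   (see [reduce_sequence()]).
#' @param K Alphabet size (number of classes).
#' @return Named numeric vector of length `K^3` summing to 1.
#' @export
#' @examples
#' ab <- canonical_alphabets()$ST_SS
#' tripeptide_composition(reduce_sequence("ACDEFACDEF", ab), alphabet_size(ab))[1:5]
tripeptide_composition <- function(reduced, K) {
  stopifnot(is.numeric(reduced), is.numeric(K), K >= 2)
  K <- as.integer(K)
  reduced <- as.integer(reduced)
  L <- length(reduced)
  if (L < 3L) abort("sequence has fewer than 3 residues; tripeptide composition undefined")
  if (any(reduced < 0L | reduced >= K)) abort("reduced symbols out of range for alphabet size K")
  # flat index of window (x,y,z) under lexicographic (x,y,z) order
  x <- reduced[1:(L - 2L)]
  y <- reduced[2:(L - 1L)]
  z <- reduced[3:L]
  idx <- x * K * K + y * K + z + 1L
  v <- numeric(K^3)
  tab <- tabulate(idx, nbins = K^3)
  v <- tab / (L - 2L)
  names(v) <- tripeptide_labels(K)
  v
}

#' @rdname tripeptide_composition
#' @export
tripeptide_labels <- function(K) {
  K <- as.integer(K)
  g <- expand.grid(z = 0:(K - 1L), y = 0:(K - 1L), x = 0:(K - 1L))
  paste(g$x, g$y, g$z, sep = "-")
}

#' Splice RTC and PSSM features into the composite RTCP vector
#'
#' Concatenates the reduced tripeptide composition (length K^3) with the
#' 20-dimensional PSSM summary, tripeptide coordinates first, giving the
#' K^3 + 20 composite feature (532 for the 8-class alphabet).
#'
#' @param rtc Named numeric RTC vector.
#' @param pssm_f Named numeric length-20 PSSM feature.
#' @param protein_id,pssm_protein_id Optional identifiers; if both given
#'   they must match.
#' @return Named numeric vector of length `length(rtc) + 20`.
#' @export
assemble_rtcp <- function(rtc, pssm_f, protein_id = NULL, pssm_protein_id = NULL) {
  stopifnot(is.numeric(rtc), is.numeric(pssm_f))
  if (length(pssm_f) != 20L) abort("PSSM feature must have length 20")
  if (!is.null(protein_id) && !is.null(pssm_protein_id) &&
      !identical(protein_id, pssm_protein_id)) {
    abort(sprintf("protein id mismatch: RTC is '%s', PSSM is '%s'",
                  protein_id, pssm_protein_id))
  }
  c(rtc, pssm_f)
}

#' Amino-acid composition
#'
#' Relative frequency of each of the 20 standard letters in a sequence
#' (non-standard letters dropped with a warning). Used for contrasting
#' stably misclassified proteins with their class.
#'
#' @param seq Amino-acid string.
#' @return Named numeric vector of length 20 (alphabetical letter order)
#'   summing to 1.
#' @export
#' @examples
#' amino_acid_composition("HQVHQV")[c("H", "Q", "V")]
amino_acid_composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  letters_v <- strsplit(toupper(seq), "")[[1]]
  nonstd <- setdiff(unique(letters_v), AA_LETTERS)
  if (length(nonstd) > 0L) {
    warn(sprintf("dropping residues with non-standard letters (%s)",
                 paste(nonstd, collapse = "")))
    letters_v <- letters_v[letters_v %in% AA_LETTERS]
  }
  if (length(letters_v) == 0L) abort("empty sequence")
  counts <- table(factor(letters_v, levels = AA_LETTERS))
  v <- as.numeric(counts) / length(letters_v)
  names(v) <- AA_LETTERS
  v
}

#' Extract per-protein feature rows
#'
#' The data-frame-first entry point for feature extraction: takes a tibble
#' of sequences (and optionally their PSSMs) and returns one feature row
#' per protein, columns named by feature coordinate. With `pssms` supplied
#' the rows are RTCP vectors (RTC block then `pssm_A..pssm_Y`); without,
#' RTC alone.
#'
#' Proteins whose sanitized sequence is shorter than 3 residues cannot
#' yield a tripeptide composition and are dropped with a warning.
#'
#' @param data Data frame with columns `id` and `seq` (see [read_fasta()]);
#'   any other columns (e.g. `label`) are carried through.
#' @param alphabet An `rtcp_alphabet` (default canonical ST_SS, the
#'   best-performing pairing of surface tension with solvent solubility).
#' @param pssms Optional named list of `rtcp_pssm` objects keyed by protein
#'   id, or `NULL` for RTC-only features. Every id in `data` must be
#'   present unless `on_missing_pssm = "skip"`.
#' @param on_missing_pssm `"abort"` (default) or `"skip"` with a warning.
#' @return A tibble: carried-through columns, then feature columns.
#' @export
#' @examples
#' d <- tibble::tibble(id = c("p1", "p2"), seq = c("ACDEFGHIK", "MNPQRSTVWY"))
#' extract_features(d, canonical_alphabets()$ST_SS)[, 1:4]
extract_features <- function(data, alphabet = canonical_alphabets()$ST_SS,
                             pssms = NULL,
                             on_missing_pssm = c("abort", "skip")) {
  stopifnot(is.data.frame(data), all(c("id", "seq") %in% names(data)),
            inherits(alphabet, "rtcp_alphabet"))
  on_missing_pssm <- match.arg(on_missing_pssm)
  if (anyDuplicated(data$id)) abort("duplicate protein ids in `data`")
  K <- alphabet_size(alphabet)

  if (!is.null(pssms)) {
    missing <- setdiff(data$id, names(pssms))
    if (length(missing) > 0L) {
      msg <- sprintf("no PSSM for %d protein(s): %s", length(missing),
                     paste(utils::head(missing, 5), collapse = ", "))
      if (on_missing_pssm == "abort") abort(msg)
      warn(paste(msg, "- skipped"))
      data <- data[!data$id %in% missing, , drop = FALSE]
    }
  }

  too_short <- nchar(gsub("[BJOUXZ]", "", toupper(data$seq))) < 3L
  if (any(too_short)) {
    warn(sprintf("dropping %d protein(s) shorter than 3 sanitized residues",
                 sum(too_short)))
    data <- data[!too_short, , drop = FALSE]
  }
  if (nrow(data) == 0L) abort("no usable proteins left")

  rows <- purrr::map2(data$id, data$seq, function(id, s) {
    rtc <- tripeptide_composition(reduce_sequence(s, alphabet), K)
    if (is.null(pssms)) return(rtc)
    assemble_rtcp(rtc, pssm_feature(pssms[[id]]),
                  protein_id = id, pssm_protein_id = pssms[[id]]$protein_id)
  })
  feat <- do.call(rbind, rows)
  dplyr::bind_cols(as_tibble(data), as_tibble(feat))
}

#' Identify feature columns of an extracted feature tibble
#'
#' @param data A tibble from [extract_features()] or with the same naming
#'   scheme (tripeptide labels `"x-y-z"`, `pssm_*`, or `pc*` columns).
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(data) {
  nm <- names(data)
  nm[grepl("^[0-9]+-[0-9]+-[0-9]+$", nm) | grepl("^pssm_[A-Z]$", nm) |
       grepl("^pc[0-9]+$", nm)]
}
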