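#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# The 20 standard amino-acid letters, alphabetical.
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# PSI-BLAST column order for PSSM matrices.
PSSM_COLS <- strsplit("ARNDCQEGHILKMFPSTWVY", "")[[1]]

#' Physicochemical amino-acid classifications
#'
#' Four three-way classifications of the 20 standard amino acids by
#' hydrophobicity, surface tension, solvent solubility and charged polarity.
#' Each is stored verbatim as printed in the source classification, even
#' where the solvent-solubility row is internally inconsistent (S, T and C
#' appear in two classes; D, N, Q and R in none) — see
#' `vignette("rtcp-methods")`.
#'
#' @return A named list of `rtcp_property` objects, each with a `name` and a
#'   character vector `classes` of three concatenated letter sets.
#' @seealso [build_alphabet()] which intersects two properties,
#'   [canonical_alphabets()] for the six published reduced alphabets.
#' @export
#' @examples
#' physicochemical_properties()$hydrophobicity
physicochemical_properties <- function() {
  defs <- list(
    hydrophobicity    = c("RKEDQN", "GASTPHY", "CVLIMFW"),
    surface_tension   = c("GQDNAHR", "KTSEC", "ILMFPWYV"),
    solvent_solubility = c("ALFCGIVW", "KTSEC", "MPSTHY"),
    charged_polarity  = c("LIFWCMVY", "PATGS", "HQRKEND")
  )
  purrr::imap(defs, function(cls, nm) {
    structure(list(name = nm, classes = cls), class = "rtcp_property")
  })
}

#' @export
print.rtcp_property <- function(x, ...) {
  cat("<physicochemical property:", x$name, ">\n")
  for (i in seq_along(x$classes)) {
    cat(sprintf("  class %d: %s\n", i, x$classes[i]))
  }
  invisible(x)
}

#' Construct a reduced amino-acid alphabet
#'
#' Builds a total, single-valued mapping of the 20 standard amino-acid
#' letters onto `K` reduced classes. Class order is as given and defines
#' class indices `0..K-1`, which are the coordinate system of the tripeptide
#' composition. A letter listed in more than one class is assigned to the
#' first class in which it occurs (first-occurrence collision policy);
#' letters in no class are appended as a trailing overflow class.
#'
#' @param name Identifier for the alphabet.
#' @param classes Character vector of concatenated uppercase letter sets,
#'   one element per class, in class-index order.
#' @return An object of class `rtcp_alphabet` with fields `name`, `classes`
#'   (letter sets after collision resolution), and `letter_map`, a named
#'   integer vector mapping each of the 20 letters to a 0-based class index.
#' @export
#' @examples
#' ab <- reduced_alphabet("toy", c("ACDEFGHIK", "LMNPQRSTVWY"))
#' alphabet_size(ab)
reduced_alphabet <- function(name, classes) {
  stopifnot(is.character(name), length(name) == 1L)
  classes <- toupper(classes)
  classes <- classes[nzchar(classes)]
  if (length(classes) < 1L) abort("alphabet needs at least one non-empty class")
  seen <- character(0)
  resolved <- character(length(classes))
  for (i in seq_along(classes)) {
    letters_i <- strsplit(classes[i], "")[[1]]
    bad <- setdiff(letters_i, AA_LETTERS)
    if (length(bad) > 0L) {
      abort(sprintf("class %d of alphabet '%s' contains non-standard letters: %s",
                    i, name, paste(bad, collapse = "")))
    }
    keep <- setdiff(letters_i, seen)       # first occurrence wins
    resolved[i] <- paste(keep, collapse = "")
    seen <- c(seen, keep)
  }
  missing <- setdiff(AA_LETTERS, seen)
  if (length(missing) > 0L) {
    resolved <- c(resolved, paste(missing, collapse = ""))
  }
  resolved <- resolved[nzchar(resolved)]
  K <- length(resolved)
  if (K < 2L || K > 20L) {
    abort(sprintf("alphabet '%s' has %d classes; need between 2 and 20", name, K))
  }
  letter_map <- integer(20)
  names(letter_map) <- AA_LETTERS
  for (i in seq_along(resolved)) {
    letter_map[strsplit(resolved[i], "")[[1]]] <- i - 1L
  }
  # partition check: every letter assigned exactly once
  sizes <- nchar(resolved)
  stopifnot(sum(sizes) == 20L, !anyDuplicated(unlist(strsplit(resolved, ""))))
  structure(list(name = name, classes = resolved, letter_map = letter_map),
            class = "rtcp_alphabet")
}

#' @rdname reduced_alphabet
#' @param alphabet An `rtcp_alphabet`.
#' @export
alphabet_size <- function(alphabet) {
  stopifnot(inherits(alphabet, "rtcp_alphabet"))
  length(alphabet$classes)
}

#' @export
print.rtcp_alphabet <- function(x, ...) {
  cat(sprintf("<reduced alphabet: %s, %d classes>\n", x$name, alphabet_size(x)))
  for (i in seq_along(x$classes)) {
    cat(sprintf("  %d: %s\n", i - 1L, x$classes[i]))
  }
  invisible(x)
}

# Verbatim class cells, top-to-bottom, for the six canonical alphabets.
# SS_CP lists L twice (ICWFLV and LH); reduced_alphabet() resolves it to the
# first occurrence, leaving H alone in the final class.
CANONICAL_CELLS <- list(
  HP_ST = c("RQND", "EK", "AGH", "ST", "PY", "C", "WIFLMV"),
  HP_SS = c("NEQRDK", "AG", "SPYHT", "CFIVWL", "M"),
  HP_CP = c("RKDQEN", "Y", "GPSTA", "H", "LFVCIWM"),
  ST_SS = c("AG", "RNDQH", "C", "ST", "KE", "MYVLFWI", "P"),
  ST_CP = c("GA", "NQDR", "H", "C", "EK", "TS", "FLWIV", "MYP"),
  SS_CP = c("ICWFLV", "AG", "RDENQK", "MY", "SPT", "LH")
)

#' The six canonical reduced amino-acid alphabets
#'
#' Returns the published reduced alphabets HP_ST, HP_SS, HP_CP, ST_SS,
#' ST_CP and SS_CP, formed by pairing the four physicochemical properties
#' (hydrophobicity, surface tension, solvent solubility, charged polarity).
#' They have 7, 5, 5, 7, 8 and 6 classes respectively and each partitions
#' the 20 standard letters.
#'
#' The class cells are stored verbatim from the published table; class
#' indices follow top-to-bottom cell order. The published property table
#' cannot regenerate all six by set intersection (its solvent-solubility
#' row is inconsistent), so these constants are authoritative here and
#' [build_alphabet()] is reserved for user-supplied properties.
#'
#' @return Named list of six [reduced_alphabet()] objects.
#' @export
#' @examples
#' canonical_alphabets()$ST_SS
#' vapply(canonical_alphabets(), alphabet_size, integer(1))
canonical_alphabets <- function() {
  purrr::imap(CANONICAL_CELLS, function(cells, nm) reduced_alphabet(nm, cells))
}

#' Intersect two physicochemical properties into a reduced alphabet
#'
#' Forms classes as the non-empty pairwise intersections of the classes of
#' `prop_a` with those of `prop_b`, ordered by (class of a, class of b).
#' Letters caught in several intersections keep their first class; letters
#' in no intersection are appended as an overflow class, so the result is
#' always a total partition of the 20 letters.
#'
#' @param prop_a,prop_b Two distinct `rtcp_property` objects (see
#'   [physicochemical_properties()]) or objects with `name` and `classes`
#'   fields of the same shape.
#' @param name Optional alphabet name; default `"A_B"` from the property names.
#' @return An `rtcp_alphabet`.
#' @export
#' @examples
#' pp <- physicochemical_properties()
#' build_alphabet(pp$hydrophobicity, pp$surface_tension)
build_alphabet <- function(prop_a, prop_b, name = NULL) {
  stopifnot(!is.null(prop_a$classes), !is.null(prop_b$classes))
  if (identical(prop_a$name, prop_b$name) &&
      identical(prop_a$classes, prop_b$classes)) {
    abort("build_alphabet() needs two distinct properties")
  }
  cells <- character(0)
  for (i in seq_along(prop_a$classes)) {
    a <- strsplit(prop_a$classes[i], "")[[1]]
    for (j in seq_along(prop_b$classes)) {
      b <- strsplit(prop_b$classes[j], "")[[1]]
      inter <- intersect(a, b)
      if (length(inter) > 0L) cells <- c(cells, paste(inter, collapse = ""))
    }
  }
  if (length(cells) < 2L) {
    abort("property intersection yields fewer than 2 classes; malformed properties")
  }
  if (is.null(name)) name <- paste(prop_a$name, prop_b$name, sep = "_")
  reduced_alphabet(name, cells)
}

#' Rewrite an amino-acid sequence in reduced-class symbols
#'
#' Maps each residue of `seq` to its 0-based class index under `alphabet`.
#' Non-standard residue letters (B, J, O, U, X, Z) have no class and are
#' dropped with a warning before mapping, so the output length equals the
#' sanitized input length.
#'
#' @param seq A single amino-acid string (case-insensitive).
#' @param alphabet An `rtcp_alphabet`.
#' @return Integer vector of class indices in `0..K-1`.
#' @export
#' @examples
#' reduce_sequence("ACDEF", canonical_alphabets()$ST_SS)
reduce_sequence <- function(seq, alphabet) {
  stopifnot(inherits(alphabet, "rtcp_alphabet"),
            is.character(seq), length(seq) == 1L)
  letters_v <- strsplit(toupper(seq), "")[[1]]
  nonstd <- setdiff(unique(letters_v), AA_LETTERS)
  if (length(nonstd) > 0L) {
    warn(sprintf("dropping %d residue(s) with non-standard letters (%s)",
                 sum(letters_v %in% nonstd), paste(nonstd, collapse = "")))
    letters_v <- letters_v[letters_v %in% AA_LETTERS]
  }
  if (length(letters_v) == 0L) abort("sequence empty after removing non-standard letters")
  unname(alphabet$letter_map[letters_v])
}

#' Read or write a plain-text alphabet definition
#'
#' One class per line, letters concatenated; line order defines class
#' indices. Lines starting with `#` and blank lines are ignored on read.
#'
#' @param alphabet An `rtcp_alphabet`.
#' @param path File path.
#' @param name Name for the alphabet read from file; defaults to the
#'   file stem.
#' @return `write_alphabet()` returns `path` invisibly; `read_alphabet()`
#'   returns an `rtcp_alphabet`.
#' @export
write_alphabet <- function(alphabet, path) {
  stopifnot(inherits(alphabet, "rtcp_alphabet"))
  writeLines(c(paste("#", alphabet$name), alphabet$classes), path)
  invisible(path)
}

#' @rdname write_alphabet
#' @export
read_alphabet <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  reduced_alphabet(name, lines)
}
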