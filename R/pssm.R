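#' Parse a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the layout produced by `psiblast -out_ascii_pssm`: header lines, a
#' column-label line carrying 40 amino-acid letters (a 20-column log-odds
#' block followed by a 20-column weighted-percentage block), then one row
#' per residue starting with its position index and residue letter, then
#' footer statistics. Only the first 20 numeric columns (the log-odds
#' block) are retained; sigmoid averaging presumes signed scores centred
#' near zero, which the percentage block is not.
#'
#' @param path Path to a PSSM file, or `NULL` if `text` is given.
#' @param text Character vector of file lines (alternative to `path`).
#' @param protein_id Identifier to attach; defaults to the file stem.
#' @return An `rtcp_pssm` object: `protein_id`, `residues` (length-L
#'   amino-acid string) and `scores`, an L x 20 numeric matrix with columns
#'   in PSI-BLAST order `ARNDCQEGHILKMFPSTWVY`.
#' @export
#' @examples
#' m <- matrix(0, 3, 20)
#' p <- new_pssm("toy", "ACE", m)
#' parsed <- parse_pssm_ascii(text = format_pssm_ascii(p))
#' identical(parsed$scores, p$scores)
parse_pssm_ascii <- function(path = NULL, text = NULL, protein_id = NULL) {
  if (is.null(text)) {
    stopifnot(is.character(path), length(path) == 1L)
    text <- readLines(path)
    if (is.null(protein_id)) protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (is.null(protein_id)) protein_id <- "unknown"
  is_data <- grepl("^\\s*[0-9]+\\s+[A-Za-z]\\s+-?[0-9]", text)
  if (!any(is_data)) abort("PSSM parse error: no data rows found")
  rows <- which(is_data)
  # data rows must be contiguous; anything after the block is footer
  body <- rows[seq_len(which.max(c(diff(rows) != 1L, TRUE)))]
  residues <- character(length(body))
  scores <- matrix(NA_real_, nrow = length(body), ncol = 20,
                   dimnames = list(NULL, PSSM_COLS))
  for (k in seq_along(body)) {
    ln <- body[k]
    fields <- strsplit(trimws(text[ln]), "\\s+")[[1]]
    if (length(fields) < 22L) {
      abort(sprintf("PSSM parse error at line %d: expected >= 22 fields, found %d",
                    ln, length(fields)))
    }
    pos <- suppressWarnings(as.integer(fields[1]))
    if (is.na(pos) || pos != k) {
      abort(sprintf("PSSM parse error at line %d: position index %s, expected %d",
                    ln, fields[1], k))
    }
    residues[k] <- toupper(fields[2])
    vals <- suppressWarnings(as.numeric(fields[3:22]))
    if (anyNA(vals)) {
      abort(sprintf("PSSM parse error at line %d: non-numeric score", ln))
    }
    scores[k, ] <- vals
  }
  new_pssm(protein_id, paste(residues, collapse = ""), scores)
}

#' Construct a PSSM object
#'
#' @param protein_id Identifier.
#' @param residues Amino-acid string of length L.
#' @param scores L x 20 numeric matrix, columns in PSI-BLAST order
#'   `ARNDCQEGHILKMFPSTWVY`.
#' @return An `rtcp_pssm` object.
#' @export
new_pssm <- function(protein_id, residues, scores) {
  stopifnot(is.character(residues), length(residues) == 1L,
            is.matrix(scores), ncol(scores) == 20L)
  L <- nchar(residues)
  if (L < 1L) abort("PSSM needs at least one residue")
  if (nrow(scores) != L) {
    abort(sprintf("PSSM row count (%d) does not match residue count (%d)",
                  nrow(scores), L))
  }
  colnames(scores) <- PSSM_COLS
  structure(list(protein_id = protein_id, residues = residues,
                 scores = scores),
            class = "rtcp_pssm")
}

#' @export
print.rtcp_pssm <- function(x, ...) {
  cat(sprintf("<PSSM: %s, L = %d>\n", x$protein_id, nrow(x$scores)))
  invisible(x)
}

#' Format or write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Emits the same layout [parse_pssm_ascii()] reads: two header lines, a
#' 40-letter column-label line, one row per residue with the 20 log-odds
#' columns, a zeroed percentage block and two trailing statistics, and a
#' footer. Round-trips through the parser losslessly for integer scores.
#'
#' @param pssm An `rtcp_pssm`.
#' @param path Output file path (for `write_pssm_ascii()`).
#' @return `format_pssm_ascii()` returns a character vector of lines;
#'   `write_pssm_ascii()` writes them and returns `path` invisibly.
#' @export
format_pssm_ascii <- function(pssm) {
  stopifnot(inherits(pssm, "rtcp_pssm"))
  header <- c("",
              "Last position-specific scoring matrix computed, weighted, and normalized")
  labels <- paste0("          ",
                   paste(sprintf("%4s", PSSM_COLS), collapse = ""),
                   " ",
                   paste(sprintf("%4s", PSSM_COLS), collapse = ""))
  res <- strsplit(pssm$residues, "")[[1]]
  body <- vapply(seq_along(res), function(i) {
    paste0(sprintf("%5d %s ", i, res[i]),
           paste(sprintf("%4d", as.integer(round(pssm$scores[i, ]))), collapse = ""),
           " ",
           paste(sprintf("%4d", rep(0L, 20)), collapse = ""),
           sprintf("  %4.2f %8.4f", 0, 0))
  }, character(1))
  footer <- c("", "                      K         Lambda", "")
  c(header, labels, body, footer)
}

#' @rdname format_pssm_ascii
#' @export
write_pssm_ascii <- function(pssm, path) {
  writeLines(format_pssm_ascii(pssm), path)
  invisible(path)
}
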