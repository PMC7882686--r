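#' Read and write protein FASTA
#'
#' `read_fasta()` loads an amino-acid FASTA file into a tibble, taking the
#' first whitespace-delimited token of each header as the id, uppercasing
#' sequences, and rejecting duplicate ids. `write_fasta()` is its inverse.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: '%s'", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) abort(sprintf("empty FASTA file: '%s'", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyNA(ids) || any(!nzchar(ids))) abort("malformed FASTA header (empty id)")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA ids: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tibble(id = ids, seq = unname(toupper(as.character(set))))
}

#' @rdname read_fasta
#' @param data Data frame with `id` and `seq` columns.
#' @export
write_fasta <- function(data, path) {
  stopifnot(is.data.frame(data), all(c("id", "seq") %in% names(data)))
  set <- Biostrings::AAStringSet(toupper(data$seq))
  names(set) <- data$id
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a directory of ASCII PSSM files
#'
#' Loads every `*.pssm` file (or those listed in an id-map TSV) and keys
#' the result by protein id — the file stem by default, or the mapping
#' given in `id_map`.
#'
#' @param dir Directory containing PSSM files.
#' @param id_map Optional TSV path or data frame with columns `id`,
#'   `file` overriding stem-based pairing.
#' @return Named list of `rtcp_pssm` objects.
#' @export
read_pssm_dir <- function(dir, id_map = NULL) {
  if (!dir.exists(dir)) abort(sprintf("no such directory: '%s'", dir))
  if (is.null(id_map)) {
    files <- list.files(dir, pattern = "\\.pssm$", full.names = TRUE)
    ids <- sub("\\.pssm$", "", basename(files))
  } else {
    if (is.character(id_map)) {
      id_map <- utils::read.delim(id_map, stringsAsFactors = FALSE)
    }
    stopifnot(all(c("id", "file") %in% names(id_map)))
    files <- file.path(dir, id_map$file)
    ids <- id_map$id
  }
  if (length(files) == 0L) abort(sprintf("no PSSM files found under '%s'", dir))
  out <- purrr::map2(files, ids,
                     function(f, id) parse_pssm_ascii(f, protein_id = id))
  names(out) <- ids
  out
}

#' Read a label TSV
#'
#' Two columns, `id` and `label` (0/1), tab-separated with a header.
#'
#' @param path TSV path.
#' @return Tibble with `id` (character) and `label` (integer).
#' @export
read_labels <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(d))) {
    abort("label file must have columns 'id' and 'label'")
  }
  lab <- as.integer(d$label)
  if (!all(lab %in% c(0L, 1L))) abort("labels must be 0/1")
  tibble(id = as.character(d$id), label = lab)
}

#' Write or read a feature matrix TSV
#'
#' One row per protein; the header carries the feature schema (and any
#' metadata columns such as `id` and `label`). Numbers are written at full
#' precision so identical inputs reproduce byte-identical files.
#'
#' @param data Feature tibble.
#' @param path Output TSV path.
#' @export
write_feature_tsv <- function(data, path) {
  stopifnot(is.data.frame(data))
  num <- vapply(data, is.numeric, logical(1)) &
    !vapply(data, is.integer, logical(1))
  out <- data
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_tibble(d)
}
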