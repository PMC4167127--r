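#' Build a validated equal-length sequence set
#'
#' The central container for scanning: a tibble with one row per sequence
#' (`id`, `seq`), all sequences the same length, ids unique. Letters are
#' uppercased; ambiguous IUPAC letters other than `N` are mapped to `N` (with
#' a message giving the count). `U` is accepted only when no `T` occurs in the
#' set (RNA), and vice versa.
#'
#' @param ids Character vector of unique record ids.
#' @param seqs Character vector of sequences (same length as `ids`).
#' @param role `"primary"` or `"control"`; stored as an attribute.
#' @return A tibble of class `mz_seqset` with attributes `L` (sequence
#'   length), `role` and `alphabet`.
#' @export
sequence_set <- function(ids, seqs, role = c("primary", "control")) {
  role <- arg_match(role)
  if (length(ids) != length(seqs) || length(ids) == 0L) {
    abort("need one id per sequence, and at least one sequence")
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(seqs)
  has_t <- any(grepl("T", seqs, fixed = TRUE))
  has_u <- any(grepl("U", seqs, fixed = TRUE))
  if (has_t && has_u) {
    abort("sequence set mixes T and U; use one alphabet")
  }
  alphabet <- if (has_u) "ACGU" else "ACGT"
  keep <- "ACGTUN"
  n_amb <- sum(nchar(seqs)) - sum(nchar(gsub(paste0("[^", keep, "]"), "", seqs)))
  if (n_amb > 0) {
    seqs <- gsub(paste0("[^", keep, "]"), "N", seqs)
    inform(paste0("mapped ", n_amb, " ambiguous letter(s) to N"))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- ids[lens != lens[1L]]
    abort(paste0("sequences must all have the same length; offending ids: ",
                 paste(head(off, 5L), collapse = ", ")))
  }
  if (lens[1L] < 1L) abort("sequences must have length >= 1")
  out <- tibble(id = ids, seq = seqs)
  structure(out, L = lens[[1L]], role = role, alphabet = alphabet,
            class = c("mz_seqset", class(out)))
}

#' Read an equal-length sequence set from FASTA
#'
#' Thin wrapper over `Biostrings::readBStringSet()` (plain or gzipped FASTA)
#' that validates and normalizes the records via [sequence_set()].
#'
#' @param path FASTA file path.
#' @param role `"primary"` or `"control"`.
#' @return An `mz_seqset` tibble.
#' @export
read_sequences <- function(path, role = c("primary", "control")) {
  role <- arg_match(role)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) abort(paste0("no FASTA records in ", path))
  ids <- sub("\\s.*$", "", names(ss))
  sequence_set(ids, as.character(ss), role = role)
}

#' Write a sequence set as FASTA
#' @param seqs An `mz_seqset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  stopifnot(inherits(seqs, "mz_seqset"))
  ss <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

seqset_L <- function(seqs) {
  L <- attr(seqs, "L", exact = TRUE)
  if (is.null(L)) L <- unique(nchar(seqs$seq))[1L]
  as.integer(L)
}

check_same_L <- function(primary, control) {
  if (seqset_L(primary) != seqset_L(control)) {
    abort(paste0("primary (L=", seqset_L(primary), ") and control (L=",
                 seqset_L(control),
                 ") sequence lengths differ; the differential model compares ",
                 "identical coordinates"))
  }
  invisible(TRUE)
}
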