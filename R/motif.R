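DNA_LETTERS <- c("A", "C", "G", "T")
RNA_LETTERS <- c("A", "C", "G", "U")

motif_letters <- function(alphabet) {
  switch(alphabet, ACGT = DNA_LETTERS, ACGU = RNA_LETTERS,
         abort(paste0("unsupported alphabet '", alphabet, "'")))
}

#' Construct a motif (position probability matrix)
#'
#' A motif is a width x 4 matrix of per-position letter probabilities over
#' `ACGT` (DNA) or `ACGU` (RNA), plus an identifier, an optional human-readable
#' name and an optional number of sites the matrix was estimated from
#' (`nsites`, used to weight the pseudocount when converting to log-odds).
#'
#' @param id Non-empty motif identifier.
#' @param probs Numeric matrix with `width` rows and 4 columns; every row must
#'   sum to 1 within `1e-3` (rows are renormalized to sum exactly 1).
#' @param name Optional display name; defaults to `id`.
#' @param alphabet `"ACGT"` (default) or `"ACGU"`.
#' @param nsites Optional positive number of sites.
#' @return An object of class `mz_motif`.
#' @examples
#' m <- motif("ex", rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
#' consensus(m)
#' @export
motif <- function(id, probs, name = id, alphabet = c("ACGT", "ACGU"),
                  nsites = NULL) {
  alphabet <- arg_match(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    abort("motif 'id' must be a non-empty string")
  }
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L || nrow(probs) < 1L) {
    abort(paste0("motif '", id, "': probability matrix must be width x 4"))
  }
  if (any(probs < 0)) {
    abort(paste0("motif '", id, "': negative probabilities"))
  }
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-3)) {
    bad <- which(abs(rs - 1) > 1e-3)[1L]
    abort(paste0("motif '", id, "': probability row ", bad, " sums to ",
                 format(rs[bad]), " (must be 1 within 1e-3)"))
  }
  probs <- probs / rs
  dimnames(probs) <- list(NULL, strsplit(alphabet, "")[[1L]])
  if (!is.null(nsites)) {
    nsites <- as.numeric(nsites)
    if (!is.finite(nsites) || nsites <= 0) abort("'nsites' must be positive")
  }
  structure(
    list(id = id, name = name, alphabet = alphabet, probs = probs,
         nsites = nsites),
    class = "mz_motif"
  )
}

#' @export
print.mz_motif <- function(x, ...) {
  cat("<mz_motif> ", x$id, if (!identical(x$name, x$id)) paste0(" (", x$name, ")"),
      "  width=", motif_width(x), "  alphabet=", x$alphabet, "\n", sep = "")
  cat("consensus:", consensus(x), "\n")
  invisible(x)
}

#' Motif width (number of positions)
#' @param m An `mz_motif`.
#' @return Integer width.
#' @export
motif_width <- function(m) nrow(m$probs)

#' Majority-letter consensus string of a motif
#' @param m An `mz_motif`.
#' @return A character scalar, one letter per motif position.
#' @export
consensus <- function(m) {
  paste(colnames(m$probs)[max.col(m$probs, ties.method = "first")],
        collapse = "")
}

#' Estimate a 0-order background from one or more sequence sets
#'
#' Counts letter frequencies over all sequences; for DNA the counts are
#' strand-symmetrized (A with T, C with G) because scanning considers both
#' strands, while RNA backgrounds are single-stranded. Ambiguous letters are
#' excluded. Each frequency is floored at `1e-3` and the vector renormalized,
#' so log-odds scores are always defined.
#'
#' @param seqs A sequence set tibble (see [read_sequences()]) or a plain
#'   character vector of sequences; pass a list of sets to pool them (e.g.
#'   primary and control).
#' @return Named numeric vector of 4 frequencies summing to 1.
#' @examples
#' compute_background(c("ACGT", "AATT"))
#' @export
compute_background <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- list(seqs)
  if (is.character(seqs)) seqs <- list(tibble(id = seq_along(seqs), seq = seqs))
  stopifnot(is.list(seqs))
  chars <- unlist(lapply(seqs, function(s) s$seq), use.names = FALSE)
  rna <- any(grepl("U", chars, fixed = TRUE))
  letters4 <- if (rna) RNA_LETTERS else DNA_LETTERS
  tab <- table(factor(strsplit(paste(chars, collapse = ""), "")[[1L]],
                      levels = letters4))
  counts <- as.numeric(tab)
  if (sum(counts) == 0) {
    abort("cannot estimate a background: sequences contain only ambiguous letters")
  }
  if (!rna) {
    # double-stranded symmetrization: A<->T, C<->G
    counts <- (counts + rev(counts)) / 2
  }
  freqs <- counts / sum(counts)
  freqs <- pmax(freqs, 1e-3)
  freqs <- freqs / sum(freqs)
  setNames(freqs, letters4)
}

check_background <- function(bg) {
  if (!is.numeric(bg) || length(bg) != 4L || any(bg <= 0) ||
      abs(sum(bg) - 1) > 1e-9) {
    abort("background must be 4 strictly positive frequencies summing to 1")
  }
  invisible(bg)
}

#' Convert a motif to a log-odds scoring matrix
#'
#' Scores are in bits: `log2((p * n + pseudo * bg) / ((n + pseudo) * bg))`
#' where `n` is the effective site count (`nsites`, defaulting to 100) and the
#' pseudocount is distributed proportionally to the background. With
#' `pseudo = 0`, zero-probability cells get a large negative finite sentinel
#' instead of `-Inf`.
#'
#' @param m An `mz_motif`.
#' @param bg Background frequencies (see [compute_background()]); default
#'   uniform.
#' @param pseudo Non-negative total pseudocount (default 0.1).
#' @return An `mz_scoring_matrix`: width x 4 matrix of bit scores with
#'   attributes `motif_id`, `alphabet` and `strand` (`"+"`).
#' @examples
#' sm <- to_log_odds(motif("ex", rbind(c(1, 0, 0, 0))), pseudo = 0)
#' sm[1, "A"]  # 2 bits against a uniform background
#' @export
to_log_odds <- function(m, bg = rep(0.25, 4), pseudo = 0.1) {
  stopifnot(inherits(m, "mz_motif"))
  check_background(bg)
  if (!is.numeric(pseudo) || length(pseudo) != 1L || pseudo < 0) {
    abort("'pseudo' must be a single non-negative number")
  }
  n_eff <- m$nsites %||% 100
  bgm <- matrix(bg, nrow = motif_width(m), ncol = 4L, byrow = TRUE)
  adj <- (m$probs * n_eff + pseudo * bgm) / (n_eff + pseudo)
  scores <- log2(adj / bgm)
  scores[!is.finite(scores)] <- NEG_SCORE
  dimnames(scores) <- dimnames(m$probs)
  structure(scores, motif_id = m$id, alphabet = m$alphabet, strand = "+",
            class = c("mz_scoring_matrix", "matrix", "array"))
}

#' Reverse complement a scoring matrix
#'
#' Reverses the position order and complements the letters, flipping the
#' strand attribute; used to score the reverse strand at forward-strand
#' coordinates. DNA only.
#'
#' @param sm An `mz_scoring_matrix`.
#' @return The reverse-complement `mz_scoring_matrix`.
#' @export
reverse_complement_matrix <- function(sm) {
  stopifnot(inherits(sm, "mz_scoring_matrix"))
  if (attr(sm, "alphabet") != "ACGT") {
    abort("reverse complement is only defined for the DNA alphabet")
  }
  out <- sm[rev(seq_len(nrow(sm))), rev(seq_len(ncol(sm))), drop = FALSE]
  colnames(out) <- DNA_LETTERS
  attr(out, "motif_id") <- attr(sm, "motif_id")
  attr(out, "alphabet") <- "ACGT"
  attr(out, "strand") <- if (attr(sm, "strand") == "+") "-" else "+"
  class(out) <- class(sm)
  out
}
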