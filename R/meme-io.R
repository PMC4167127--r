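#' Parse motifs from MEME-format text
#'
#' Supports the minimal (letter-probability) dialect of the MEME motif format:
#' a `MEME version` line, optional `ALPHABET=`, `strands:` and
#' `Background letter frequencies` lines, and `MOTIF` blocks each containing a
#' `letter-probability matrix:` header followed by the matrix rows. Other
#' blocks (e.g. log-odds matrices, URLs) are ignored with a warning.
#'
#' @param path Path to a MEME motif file, or a character vector of lines
#'   passed via `text`.
#' @param text Optional character scalar/vector with the document itself.
#' @return A list of [motif()] objects (class `mz_motif_list`), with the
#'   file's background frequencies (if declared) in attribute `background`.
#' @examples
#' txt <- c("MEME version 4", "", "MOTIF m1", "letter-probability matrix: alength= 4 w= 2",
#'          " 1 0 0 0", " 0 1 0 0")
#' read_meme(text = txt)
#' @export
read_meme <- function(path, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    readLines(path, warn = FALSE)
  }
  lines <- trimws(lines)
  if (!any(grepl("^MEME version", lines, ignore.case = TRUE))) {
    abort("not a MEME motif document: missing 'MEME version' line")
  }

  alphabet <- "ACGT"
  al_line <- grep("^ALPHABET\\s*=", lines, value = TRUE)
  if (length(al_line)) {
    al <- toupper(gsub("\\s", "", sub("^ALPHABET\\s*=", "", al_line[1L])))
    if (!al %in% c("ACGT", "ACGU")) {
      abort(paste0("unsupported ALPHABET '", al, "' (only ACGT/ACGU)"))
    }
    alphabet <- al
  }

  background <- NULL
  bg_at <- grep("^Background letter frequencies", lines, ignore.case = TRUE)
  if (length(bg_at) && bg_at[1L] < length(lines)) {
    toks <- strsplit(lines[bg_at[1L] + 1L], "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks[c(FALSE, TRUE)]))
    if (length(vals) == 4L && !anyNA(vals)) {
      background <- setNames(vals, toks[c(TRUE, FALSE)])
    }
  }

  motif_at <- grep("^MOTIF\\b", lines)
  motifs <- vector("list", length(motif_at))
  ignored <- 0L
  bounds <- c(motif_at, length(lines) + 1L)
  for (k in seq_along(motif_at)) {
    block <- lines[motif_at[k]:(bounds[k + 1L] - 1L)]
    toks <- strsplit(block[1L], "\\s+")[[1L]]
    if (length(toks) < 2L) abort("MOTIF line without an identifier")
    id <- toks[2L]
    name <- if (length(toks) >= 3L) toks[3L] else id
    hdr_at <- grep("^letter-probability matrix:", block)
    if (!length(hdr_at)) {
      abort(paste0("motif '", id, "': no letter-probability matrix block"))
    }
    hdr <- block[hdr_at[1L]]
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
    if (is.na(w)) abort(paste0("motif '", id, "': matrix header lacks w="))
    nsites <- if (grepl("nsites=", hdr)) {
      as.numeric(sub(".*nsites=\\s*([0-9.eE+-]+).*", "\\1", hdr))
    } else NULL
    rows <- block[-seq_len(hdr_at[1L])]
    rows <- rows[nzchar(rows)]
    rows <- rows[grepl("^[0-9.eE+ \t-]+$", rows)]
    if (length(rows) < w) {
      abort(paste0("motif '", id, "': expected ", w, " matrix rows, found ",
                   length(rows)))
    }
    extra <- length(rows) - w
    if (extra > 0) ignored <- ignored + 1L
    vals <- lapply(rows[seq_len(w)], function(l) {
      as.numeric(strsplit(l, "\\s+")[[1L]])
    })
    if (any(lengths(vals) != 4L)) {
      abort(paste0("motif '", id, "': matrix rows must have 4 columns"))
    }
    motifs[[k]] <- motif(id, do.call(rbind, vals), name = name,
                         alphabet = alphabet, nsites = nsites)
  }
  other <- setdiff(grep("^(log-odds matrix:|URL\\b)", lines), integer(0))
  if (length(other) || ignored) {
    warn("ignored non-letter-probability content in MEME document")
  }
  structure(motifs, class = "mz_motif_list", background = background,
            alphabet = alphabet)
}

#' @export
print.mz_motif_list <- function(x, ...) {
  cat("<mz_motif_list> ", length(x), " motif(s), alphabet ",
      attr(x, "alphabet") %||% "ACGT", "\n", sep = "")
  for (m in x) cat("  ", m$id, "  w=", motif_width(m), "  ", consensus(m),
                   "\n", sep = "")
  invisible(x)
}

#' Write motifs in MEME format
#'
#' Writes the same minimal dialect that [read_meme()] reads, so motifs
#' round-trip exactly (probabilities at full precision).
#'
#' @param motifs An `mz_motif_list`, a list of `mz_motif`, or one `mz_motif`.
#' @param path Output file path.
#' @param background Optional 4 background frequencies to declare.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, background = NULL) {
  if (inherits(motifs, "mz_motif")) motifs <- list(motifs)
  stopifnot(all(vapply(motifs, inherits, logical(1), "mz_motif")))
  alphabet <- if (length(motifs)) motifs[[1L]]$alphabet else "ACGT"
  out <- c("MEME version 4", "", paste0("ALPHABET= ", alphabet), "",
           "strands: + -", "")
  if (!is.null(background)) {
    out <- c(out, "Background letter frequencies",
             paste(rbind(motif_letters(alphabet),
                         format(background, digits = 6)), collapse = " "),
             "")
  }
  for (m in motifs) {
    hdr <- paste0("letter-probability matrix: alength= 4 w= ", motif_width(m),
                  if (!is.null(m$nsites)) paste0(" nsites= ", m$nsites))
    rows <- apply(m$probs, 1L, function(p) {
      paste(sprintf("%.8f", p), collapse = "  ")
    })
    out <- c(out, paste("MOTIF", m$id, if (!identical(m$name, m$id)) m$name),
             hdr, rows, "")
  }
  writeLines(out, path)
  invisible(path)
}

as_motif_list <- function(motifs) {
  if (inherits(motifs, "mz_motif")) motifs <- list(motifs)
  if (!length(motifs) || !all(vapply(motifs, inherits, logical(1), "mz_motif"))) {
    abort("expected one or more mz_motif objects")
  }
  if (!inherits(motifs, "mz_motif_list")) {
    class(motifs) <- "mz_motif_list"
  }
  motifs
}
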