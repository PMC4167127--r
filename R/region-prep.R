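#' Read ENCODE narrowPeak intervals
#'
#' narrowPeak is BED6+4: chrom, start, end (0-based half-open), name, score,
#' strand, signalValue, pValue, qValue, peak (summit offset from `start`, -1
#' when absent). Lines with a different column count raise an error naming the
#' line.
#'
#' @param path narrowPeak file path.
#' @return A tibble of intervals: `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal`, `pvalue`, `qvalue`, `summit` (`NA` when the offset is
#'   -1).
#' @export
read_narrowpeak <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 10L)
  if (length(bad)) {
    abort(paste0("narrowPeak requires 10 tab-separated columns; line ",
                 bad[1L], " has ", lengths(fields)[bad[1L]]))
  }
  m <- do.call(rbind, fields)
  summit <- as.integer(m[, 10L])
  tibble(
    chrom = m[, 1L],
    start = as.integer(m[, 2L]),
    end = as.integer(m[, 3L]),
    name = m[, 4L],
    score = as.numeric(m[, 5L]),
    strand = m[, 6L],
    signal = as.numeric(m[, 7L]),
    pvalue = as.numeric(m[, 8L]),
    qvalue = as.numeric(m[, 9L]),
    summit = ifelse(summit < 0L, NA_integer_, summit)
  )
}

#' Fixed-size windows centered on interval midpoints
#'
#' Window `[mid - size/2, mid + size/2)` with `mid = floor((start + end) / 2)`.
#' Windows running off the start of a chromosome (or past its end, when
#' `chrom_sizes` is given) are dropped with a message.
#'
#' @param peaks Interval tibble with `chrom`, `start`, `end` (0-based
#'   half-open); extra columns are carried through.
#' @param size Even window size in bp (default 500).
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return A tibble of window intervals.
#' @export
centered_windows <- function(peaks, size = 500L, chrom_sizes = NULL) {
  if (size %% 2L != 0L) abort("window 'size' must be even")
  mid <- (peaks$start + peaks$end) %/% 2L
  out <- peaks
  out$start <- mid - size %/% 2L
  out$end <- mid + size %/% 2L
  ok <- out$start >= 0L
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[out$chrom])
    ok <- ok & !is.na(lim) & out$end <= lim
  }
  if (any(!ok)) {
    inform(paste0("dropped ", sum(!ok), " window(s) extending past chromosome bounds"))
  }
  out[ok, , drop = FALSE]
}

#' Split TSSs into peak-proximal ("bound") and distal ("unbound") promoters
#'
#' A TSS is bound when the distance from its position to the nearest peak
#' interval (0 if inside; otherwise the edge-to-point base-pair distance) is
#' at most `radius`. Both groups are returned as fixed-size windows centered
#' on the TSS, strand preserved.
#'
#' @param tss Tibble of 1-bp stranded intervals (`chrom`, `start`, `end =
#'   start + 1`, `strand`); the TSS position is `start`.
#' @param peaks Interval tibble (e.g. from [read_narrowpeak()]).
#' @param radius Proximity radius in bp (default 1000).
#' @param window Window size in bp for the output promoters (default 500).
#' @return A list with window tibbles `bound` and `unbound`; together they
#'   partition the input.
#' @export
split_tss_by_proximity <- function(tss, peaks, radius = 1000L, window = 500L) {
  if (radius <= 0) abort("'radius' must be positive")
  gr_t <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(tss$start + 1L, tss$start + 1L))
  gr_p <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
  dist <- rep(Inf, nrow(tss))
  if (length(gr_p)) {
    hits <- GenomicRanges::distanceToNearest(gr_t, gr_p)
    qi <- S4Vectors::queryHits(hits)
    # GRanges distance counts the gap; the edge-to-point distance is gap + 1
    # for disjoint ranges and 0 for overlap
    ov <- GenomicRanges::countOverlaps(gr_t, gr_p) > 0L
    d <- S4Vectors::mcols(hits)$distance
    dist[qi] <- ifelse(ov[qi], 0, d + 1)
  }
  bound <- dist <= radius
  mk <- function(rows) {
    out <- tss[rows, , drop = FALSE]
    pos <- out$start
    out$start <- pos - window %/% 2L
    out$end <- pos + window %/% 2L
    out
  }
  list(bound = mk(bound), unbound = mk(!bound))
}

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract window sequences from a genome FASTA
#'
#' Loads the genome (plain or gzipped FASTA; case preserved), extracts each
#' window, optionally reverse-complements minus-strand windows, and returns a
#' validated equal-length sequence set. Windows on missing contigs or beyond
#' contig bounds are skipped with a message. Lowercase (repeat-masked) bases
#' are uppercased, or converted to `N` first when `keep_masked_as_n = TRUE`.
#'
#' @param windows Window tibble (`chrom`, `start`, `end`, optional `strand`,
#'   `name`), 0-based half-open, all the same width.
#' @param genome Path to a FASTA file, or a named character vector /
#'   `Biostrings::BStringSet` of contigs.
#' @param stranded Reverse-complement minus-strand windows (default `FALSE`).
#' @param keep_masked_as_n Convert soft-masked (lowercase) bases to `N`.
#' @param role Role for the resulting sequence set.
#' @return An `mz_seqset` tibble.
#' @export
extract_sequences <- function(windows, genome, stranded = FALSE,
                              keep_masked_as_n = FALSE,
                              role = c("primary", "control")) {
  role <- arg_match(role)
  contigs <- if (is.character(genome) && length(genome) == 1L &&
                 file.exists(genome)) {
    ss <- Biostrings::readBStringSet(genome)
    setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else if (inherits(genome, "XStringSet")) {
    setNames(as.character(genome), names(genome))
  } else {
    genome
  }
  clen <- nchar(contigs)
  ok <- windows$chrom %in% names(contigs) & windows$start >= 0L &
    windows$end <= clen[windows$chrom] & !is.na(clen[windows$chrom])
  if (any(!ok)) {
    inform(paste0("skipped ", sum(!ok),
                  " window(s) on missing contigs or beyond contig bounds"))
  }
  w <- windows[ok, , drop = FALSE]
  if (nrow(w) == 0L) abort("no windows could be extracted")
  seqs <- unname(substr(contigs[w$chrom], w$start + 1L, w$end))
  if (keep_masked_as_n) seqs <- gsub("[a-z]", "N", seqs)
  if (stranded && "strand" %in% names(w)) {
    minus <- !is.na(w$strand) & w$strand == "-"
    seqs[minus] <- revcomp_chr(toupper(seqs[minus]))
  }
  ids <- if ("name" %in% names(w) && !anyDuplicated(w$name)) {
    w$name
  } else {
    paste0(w$chrom, ":", w$start, "-", w$end,
           if ("strand" %in% names(w)) paste0("(", w$strand, ")") else "")
  }
  sequence_set(ids, toupper(seqs), role = role)
}
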