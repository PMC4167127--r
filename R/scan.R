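encode_seqset <- function(seqs, alphabet = "ACGT") {
  letters4 <- motif_letters(alphabet)
  lut <- integer(256)
  lut[utf8ToInt(paste(letters4, collapse = "")) -
        utf8ToInt(" ") + 1L] <- seq_len(4L)
  codes <- unlist(lapply(seqs$seq, utf8ToInt), use.names = FALSE)
  m <- matrix(lut[codes - utf8ToInt(" ") + 1L], nrow = nrow(seqs), byrow = TRUE)
  m
}

# score every window start of every sequence: rows sequences, cols the
# N = L - w + 1 forward-coordinate starts; ambiguous bases poison a window
# with the NEG_SCORE sentinel
score_windows <- function(codes, sm) {
  w <- nrow(sm)
  L <- ncol(codes)
  if (L < w) abort("sequences are shorter than the motif width")
  N <- L - w + 1L
  S <- nrow(codes)
  acc <- matrix(0, S, N)
  for (i in seq_len(w)) {
    row_scores <- c(NEG_SCORE, sm[i, ])
    acc <- acc + matrix(row_scores[codes[, i:(i + N - 1L), drop = FALSE] + 1L],
                        S, N)
  }
  acc
}

#' Find the best motif match in one sequence
#'
#' Scores every window start (and optionally the reverse strand, at
#' forward-strand coordinates) and returns the maximal-scoring site with
#' score at or above the threshold, or `NULL`. Ties are broken uniformly at
#' random using the current RNG state, so results are reproducible under a
#' seed and unbiased with respect to position.
#'
#' @param seq A single sequence string.
#' @param sm Forward-strand `mz_scoring_matrix` (see [to_log_odds()]).
#' @param strands `"both"` (default, DNA) or `"single"`.
#' @param threshold Minimum score in bits.
#' @return A one-row tibble (`start`, `strand`, `score`) with 0-based `start`
#'   of the leftmost matched forward-strand base, or `NULL` if no window
#'   qualifies.
#' @export
best_site <- function(seq, sm, strands = c("both", "single"), threshold = 5) {
  strands <- arg_match(strands)
  ss <- sequence_set("q", seq)
  scan <- scan_best_sites(ss, sm, strands = strands, threshold = threshold,
                          seed = NULL)
  if (nrow(scan) == 0L) return(NULL)
  scan[, c("start", "strand", "score")]
}

#' Scan a sequence set for per-sequence best motif matches
#'
#' For each sequence stores at most one site: the best-scoring window over all
#' starts (and both strands for DNA when `strands = "both"`), kept only if its
#' score reaches `threshold`. `N = L - width + 1` counts forward-coordinate
#' start positions once regardless of strand mode, so the binomial trial space
#' is identical across strand modes; a minus-strand site is indexed by its
#' leftmost forward-strand base.
#'
#' @param seqs An `mz_seqset` tibble (data-frame-first, pipeable).
#' @param motif An `mz_motif`, or an already-built forward
#'   `mz_scoring_matrix`.
#' @param bg Background frequencies; default estimated from `seqs` via
#'   [compute_background()]. Ignored when `motif` is a scoring matrix.
#' @param strands `"both"` (default) or `"single"` (forward only; forced for
#'   RNA).
#' @param threshold Score threshold in bits (default 5); `-Inf` keeps every
#'   sequence's best site.
#' @param seed Integer seed for the random tie-break (recorded in the result);
#'   `NULL` uses the current RNG state.
#' @param pseudo Pseudocount for [to_log_odds()].
#' @return An `mz_scan` tibble with columns `seq_index`, `seq_id`, `start`
#'   (0-based), `strand`, `score`, and attributes `motif_id`, `motif_width`,
#'   `N`, `L`, `n_seq`, `threshold`, `strands`, `seed`,
#'   `n_threshold_tests` (1 for a fixed threshold).
#' @examples
#' s <- sequence_set(c("a", "b"), c("TTACGG", "TTTTTT"))
#' m <- motif("ac", rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
#' scan_best_sites(s, m, bg = rep(0.25, 4), threshold = 1, seed = 1)
#' @export
scan_best_sites <- function(seqs, motif, bg = NULL,
                            strands = c("both", "single"), threshold = 5,
                            seed = 1L, pseudo = 0.1) {
  strands <- arg_match(strands)
  stopifnot(is.data.frame(seqs))
  if (inherits(motif, "mz_scoring_matrix")) {
    sm <- motif
  } else {
    stopifnot(inherits(motif, "mz_motif"))
    if (is.null(bg)) bg <- compute_background(seqs)
    sm <- to_log_odds(motif, bg, pseudo = pseudo)
  }
  alphabet <- attr(sm, "alphabet")
  if (alphabet == "ACGU" && strands == "both") {
    inform("RNA motif: scanning the given strand only")
    strands <- "single"
  }
  codes <- encode_seqset(seqs, alphabet)
  fwd <- score_windows(codes, sm)
  rev_ <- if (strands == "both") {
    score_windows(codes, reverse_complement_matrix(sm))
  } else NULL
  N <- ncol(fwd)
  S <- nrow(codes)

  pick_sites <- function() {
    idx_seq <- integer(0); starts <- integer(0)
    strand <- character(0); score <- numeric(0)
    for (i in seq_len(S)) {
      v <- if (is.null(rev_)) fwd[i, ] else c(fwd[i, ], rev_[i, ])
      mx <- max(v)
      if (mx < threshold || mx <= NEG_SCORE / 2) next
      hits <- which(v == mx)
      pick <- if (length(hits) > 1L) hits[sample.int(length(hits), 1L)] else hits
      idx_seq <- c(idx_seq, i)
      starts <- c(starts, (pick - 1L) %% N)
      strand <- c(strand, if (pick > N) "-" else "+")
      score <- c(score, mx)
    }
    tibble(seq_index = idx_seq, seq_id = seqs$id[idx_seq],
           start = as.integer(starts), strand = strand, score = score)
  }
  out <- if (is.null(seed)) pick_sites() else withr::with_seed(seed, pick_sites())
  new_scan(out, motif_id = attr(sm, "motif_id"), motif_width = nrow(sm),
           N = N, L = ncol(codes), n_seq = S, threshold = threshold,
           strands = strands, seed = seed)
}

new_scan <- function(tbl, motif_id, motif_width, N, L, n_seq, threshold,
                     strands, seed, n_threshold_tests = 1L) {
  structure(tbl, motif_id = motif_id, motif_width = as.integer(motif_width),
            N = as.integer(N), L = as.integer(L), n_seq = as.integer(n_seq),
            threshold = threshold, strands = strands, seed = seed,
            n_threshold_tests = as.integer(n_threshold_tests),
            class = c("mz_scan", class(tibble())))
}

#' Assemble a scan result from known best-site starts
#'
#' Programmatic constructor used by simulations and tests: wraps a vector of
#' best-site start positions as an `mz_scan` without scanning.
#'
#' @param starts Integer vector of 0-based start positions (one per matched
#'   sequence).
#' @param N Number of possible start positions per sequence.
#' @param n_seq Total number of sequences scanned (default `length(starts)`).
#' @param motif_id,motif_width,L,threshold Metadata (defaults are
#'   placeholders; `L` defaults to `N + motif_width - 1`).
#' @return An `mz_scan` tibble.
#' @export
scan_result <- function(starts, N, n_seq = length(starts), motif_id = "motif",
                        motif_width = 1L, L = NULL, threshold = -Inf) {
  starts <- as.integer(starts)
  if (length(starts) && (min(starts) < 0L || max(starts) > N - 1L)) {
    abort("starts must lie in [0, N - 1]")
  }
  tbl <- tibble(seq_index = seq_along(starts),
                seq_id = as.character(seq_along(starts)),
                start = starts, strand = "+", score = NA_real_)
  new_scan(tbl, motif_id = motif_id, motif_width = motif_width, N = N,
           L = L %||% (N + motif_width - 1L), n_seq = n_seq,
           threshold = threshold, strands = "single", seed = NULL)
}

#' Choose the motif score threshold that maximizes local enrichment
#'
#' Candidate thresholds are the distinct per-sequence best-match scores
#' observed in the primary set with no threshold (thinned to at most 100 by
#' quantiles). For each candidate the qualifying sites are re-derived and the
#' minimal adjusted enrichment p-value computed, with the multiple-test count
#' multiplied by the number of candidates evaluated (a conservative accounting
#' of the threshold search); the candidate minimizing the adjusted p-value is
#' returned (ties favor the lower threshold, i.e. more sites).
#'
#' @inheritParams scan_best_sites
#' @param mode,min_width,max_width,width_step Region grid used to evaluate
#'   candidates; see [enumerate_regions()].
#' @return A list: `threshold` (bits), `scan` (the `mz_scan` at that
#'   threshold, its `n_threshold_tests` attribute set to the number of
#'   candidates), `n_thresholds_tested`, and `p_adj` (the minimized adjusted
#'   p-value), or `NULL` when no sequence has a scorable window.
#' @export
optimize_threshold <- function(seqs, motif, bg = NULL,
                               strands = c("both", "single"), seed = 1L,
                               mode = c("central", "local"), min_width = 10L,
                               max_width = NULL, width_step = 5L,
                               pseudo = 0.1) {
  strands <- arg_match(strands)
  mode <- arg_match(mode)
  scan0 <- scan_best_sites(seqs, motif, bg = bg, strands = strands,
                           threshold = -Inf, seed = seed, pseudo = pseudo)
  if (nrow(scan0) == 0L) return(NULL)
  N <- attr(scan0, "N")
  cand <- sort(unique(scan0$score))
  if (length(cand) > 100L) {
    cand <- sort(unique(quantile(cand, probs = seq(0, 1, length.out = 100L),
                                 type = 1L, names = FALSE)))
  }
  regions <- enumerate_regions(N, mode = mode, min_width = min_width,
                               max_width = max_width %||% N,
                               width_step = width_step)
  n_cand <- length(cand)
  n_tests <- nrow(regions) * n_cand
  best <- NULL
  for (t in cand) {
    starts <- scan0$start[scan0$score >= t]
    if (!length(starts)) next
    lp_min <- min_region_log_pvalue(starts, N, regions)
    p_adj <- adjust_from_log(lp_min, n_tests)$p_adj
    if (is.null(best) || p_adj < best$p_adj) {
      best <- list(threshold = t, p_adj = p_adj)
    }
  }
  if (is.null(best)) return(NULL)
  keep <- scan0$score >= best$threshold
  scan <- new_scan(scan0[keep, , drop = FALSE], motif_id = attr(scan0, "motif_id"),
                   motif_width = attr(scan0, "motif_width"), N = N,
                   L = attr(scan0, "L"), n_seq = attr(scan0, "n_seq"),
                   threshold = best$threshold, strands = strands, seed = seed,
                   n_threshold_tests = n_cand)
  list(threshold = best$threshold, scan = scan,
       n_thresholds_tested = n_cand, p_adj = best$p_adj)
}
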