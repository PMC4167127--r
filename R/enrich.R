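#' Success probability of a sub-region under the uniform prior
#'
#' With `M` possible motif start positions in the sub-region out of `N` in the
#' whole sequence, a uniformly placed best site falls in the sub-region with
#' probability `r = M / N`.
#'
#' @param M Number of start positions in the sub-region (1..N).
#' @param N Number of start positions in a whole sequence.
#' @return `M / N`.
#' @export
success_probability <- function(M, N) {
  if (any(M < 1) || any(M > N)) abort("require 1 <= M <= N")
  M / N
}

#' Upper-tail binomial enrichment p-value
#'
#' Probability of at least `s` successes in `S` Bernoulli trials with success
#' probability `r`; evaluated in log space via `stats::pbinom` so that
#' extremely small values keep a usable magnitude.
#'
#' @param s Observed successes (best matches in the sub-region).
#' @param S Trials (sequences with a best match).
#' @param r Per-trial success probability.
#' @param log.p Return the natural log of the p-value.
#' @return `P(X >= s)` for `X ~ Binomial(S, r)` (vectorized).
#' @examples
#' binomial_pvalue(5, 10, 0.2)
#' @export
binomial_pvalue <- function(s, S, r, log.p = FALSE) {
  if (any(s < 0) || any(s > S) || any(r < 0) || any(r > 1)) {
    abort("require 0 <= s <= S and 0 <= r <= 1")
  }
  pbinom(s - 1, S, r, lower.tail = FALSE, log.p = log.p)
}

# stable adjustment from a natural-log raw p-value; returns both the adjusted
# p and its natural log, switching to the p_adj ~ n * p' regime when (1-p')^n
# would lose all precision
adjust_from_log <- function(lp, n) {
  p <- exp(lp)
  p_adj <- ifelse(p > 1e-12,
                  -expm1(n * log1p(-p)),
                  -expm1(-exp(log(n) + lp)))
  ln_adj <- ifelse(p_adj > 0, log(p_adj), log(n) + lp)
  list(p_adj = pmin(p_adj, 1), ln_p_adj = pmin(ln_adj, 0))
}

#' Adjust a raw sub-region p-value for the number of sub-regions tested
#'
#' Under the conservative assumption that the `n` tested sub-regions are
#' independent, the probability that at least one reaches raw p-value `p_raw`
#' is `1 - (1 - p_raw)^n`, evaluated with `log1p`/`expm1` for stability.
#'
#' @param p_raw Raw binomial (or Fisher) p-value in \[0, 1\].
#' @param n Number of tests (>= 1).
#' @return Adjusted p-value in \[0, 1\] (vectorized).
#' @examples
#' adjust_pvalue(0.01, 100)
#' @export
adjust_pvalue <- function(p_raw, n) {
  if (any(p_raw < 0) || any(p_raw > 1)) abort("p_raw must be in [0, 1]")
  if (any(n < 1)) abort("n must be >= 1")
  out <- ifelse(p_raw > 0, adjust_from_log(log(p_raw), n)$p_adj, 0)
  pmin(pmax(out, 0), 1)
}

#' Motif E-value
#'
#' The expected number of motifs reaching the adjusted p-value: `p_adj` times
#' the number of motifs in the input compendium. Its ceiling is the compendium
#' size (since `p_adj <= 1`).
#'
#' @param p_adj Adjusted p-value.
#' @param n_motifs Number of motifs in the compendium (>= 1).
#' @return `p_adj * n_motifs` (vectorized).
#' @export
motif_evalue <- function(p_adj, n_motifs) {
  if (any(n_motifs < 1)) abort("n_motifs must be >= 1")
  p_adj * n_motifs
}

#' Enumerate candidate sub-regions
#'
#' A sub-region is a half-open span `[start, start + M)` of motif start
#' positions. In `"local"` mode every feasible start is paired with every
#' width in the grid; in `"central"` mode only sub-regions exactly centered in
#' the sequence are kept (widths sharing the parity of `N`, start
#' `(N - M) / 2`), one per admissible width. The number of rows returned is
#' the sub-region contribution to the multiple-test count `n`.
#'
#' @param N Number of start positions per sequence.
#' @param mode `"central"` or `"local"`.
#' @param min_width,max_width,width_step Width grid (defaults 10, `N`, 5; all
#'   in start-position units).
#' @return A tibble (`start`, `width`) with attributes `N` and `mode`.
#' @examples
#' enumerate_regions(5, "central", min_width = 1, width_step = 1)
#' @export
enumerate_regions <- function(N, mode = c("central", "local"), min_width = 10L,
                              max_width = NULL, width_step = 5L) {
  mode <- arg_match(mode)
  N <- as.integer(N)
  max_width <- as.integer(max_width %||% N)
  min_width <- as.integer(min_width)
  if (min_width < 1L || min_width > max_width || max_width > N) {
    abort("require 1 <= min_width <= max_width <= N")
  }
  widths <- seq.int(min_width, max_width, by = as.integer(width_step))
  if (mode == "central") {
    widths <- widths[(N - widths) %% 2L == 0L]
    if (!length(widths)) {
      abort("empty central grid: no width in the grid shares the parity of N")
    }
    out <- tibble(start = (N - widths) %/% 2L, width = widths)
  } else {
    out <- tibble(
      start = unlist(lapply(widths, function(M) 0:(N - M)), use.names = FALSE),
      width = rep.int(widths, N - widths + 1L)
    )
  }
  structure(out, N = N, mode = mode,
            class = c("mz_regions", class(tibble())))
}

#' Count best matches inside a sub-region
#'
#' @param scan An `mz_scan` (or any tibble with a 0-based `start` column).
#' @param start,width Sub-region `[start, start + width)` in start-position
#'   units.
#' @return Integer count of sites with `start` in the span.
#' @export
count_in_region <- function(scan, start, width) {
  sum(scan$start >= start & scan$start < start + width)
}

# vectorized per-region success counts via a cumulative histogram of starts
region_counts <- function(starts, N, regions) {
  cs <- c(0L, cumsum(tabulate(starts + 1L, nbins = N)))
  cs[regions$start + regions$width + 1L] - cs[regions$start + 1L]
}

min_region_log_pvalue <- function(starts, N, regions) {
  s <- region_counts(starts, N, regions)
  min(binomial_pvalue(s, length(starts), regions$width / N, log.p = TRUE))
}

#' Greedily select non-overlapping significant sub-regions
#'
#' Keeps rows with `evalue <= alpha_evalue`, sorts by increasing raw p-value
#' (ties: smaller width, then smaller start) and emits each sub-region in turn
#' unless it overlaps an already-emitted one.
#'
#' @param results A tibble with columns `start`, `width`, `p_raw`, `evalue`
#'   (all for one motif).
#' @param alpha_evalue Significance gate on the E-value (default 10).
#' @return The selected rows, in emission order.
#' @export
select_nonoverlapping <- function(results, alpha_evalue = 10) {
  res <- results[results$evalue <= alpha_evalue, , drop = FALSE]
  if (nrow(res) == 0L) return(res)
  res <- res[order(res$p_raw, res$width, res$start), , drop = FALSE]
  kept_start <- integer(0)
  kept_end <- integer(0)
  keep <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    a <- res$start[i]
    b <- a + res$width[i]
    if (all(a >= kept_end | b <= kept_start)) {
      keep[i] <- TRUE
      kept_start <- c(kept_start, a)
      kept_end <- c(kept_end, b)
    }
  }
  res[keep, , drop = FALSE]
}

#' Local enrichment analysis of one motif's best matches
#'
#' Enumerates candidate sub-regions, computes each sub-region's binomial
#' enrichment p-value (`s` successes of `S` trials at `r = M/N`), adjusts for
#' the `n = (number of sub-regions) x (number of score thresholds tested)`
#' multiple tests, converts to E-values against the motif compendium size, and
#' greedily reports non-overlapping significant sub-regions (the single best
#' sub-region in central mode).
#'
#' @param scan An `mz_scan` from [scan_best_sites()] (data-frame-first).
#' @param mode `"central"` (default) or `"local"`.
#' @param min_width,max_width,width_step Sub-region width grid in
#'   start-position units; see [enumerate_regions()].
#' @param n_motifs Compendium size used for E-values (default 1).
#' @param n_threshold_tests Number of score thresholds tested (defaults to the
#'   scan's `n_threshold_tests` attribute, 1 for a fixed threshold).
#' @param alpha_evalue E-value gate for reporting (default 10).
#' @param regions Optional precomputed [enumerate_regions()] tibble (must
#'   match `N`), to amortize enumeration across motifs.
#' @param all_regions If `TRUE`, return every candidate sub-region untested
#'   for significance (no gate, no greedy selection); used for calibration
#'   and mode-equivalence checks.
#' @return An `mz_enrich` tibble with one row per reported sub-region:
#'   `motif_id`, `start`, `width`, `region_center`, `region_width` (bp
#'   relative to the sequence center), `s`, `S`, `r`, `p_raw`, `log_p_raw`,
#'   `n_tests`, `p_adj`, `log_p_adj`, `evalue`. Attribute `best` holds the
#'   same statistics for the overall best sub-region whether or not it passed
#'   the gate; attributes `N`, `S`, `mode`, `n_tests`, `n_motifs`,
#'   `regions_tested` describe the analysis.
#' @export
enrich_local <- function(scan, mode = c("central", "local"), min_width = 10L,
                         max_width = NULL, width_step = 5L, n_motifs = 1L,
                         n_threshold_tests = NULL, alpha_evalue = 10,
                         regions = NULL, all_regions = FALSE) {
  mode <- arg_match(mode)
  stopifnot(is.data.frame(scan))
  N <- attr(scan, "N", exact = TRUE)
  if (is.null(N)) abort("'scan' lacks an N attribute; build it with scan_best_sites()/scan_result()")
  n_threshold_tests <- n_threshold_tests %||%
    attr(scan, "n_threshold_tests", exact = TRUE) %||% 1L
  S <- nrow(scan)
  motif_id <- attr(scan, "motif_id", exact = TRUE) %||% "motif"
  if (is.null(regions)) {
    regions <- enumerate_regions(N, mode = mode, min_width = min_width,
                                 max_width = max_width %||% N,
                                 width_step = width_step)
  } else if (!is.null(attr(regions, "N")) && attr(regions, "N") != N) {
    abort("precomputed 'regions' were enumerated for a different N")
  }
  n_tests <- nrow(regions) * n_threshold_tests
  if (S == 0L) {
    inform(paste0("motif ", motif_id, ": no sequences with a best match; skipped"))
    empty <- enrich_tibble(motif_id, regions[0, ], integer(0), S, N,
                           numeric(0), n_tests, n_motifs)
    return(new_enrich(empty, motif_id, N, S, mode, n_tests, n_motifs,
                      nrow(regions), best = NULL))
  }
  s <- region_counts(scan$start, N, regions)
  lp <- binomial_pvalue(s, S, regions$width / N, log.p = TRUE)
  if (all_regions) {
    tbl <- enrich_tibble(motif_id, regions, s, S, N, lp, n_tests, n_motifs)
    ord <- order(tbl$p_raw, tbl$width, tbl$start)
    best <- as.list(tbl[ord[1L], ])
    return(new_enrich(tbl, motif_id, N, S, mode, n_tests, n_motifs,
                      nrow(regions), best = best))
  }
  ord <- order(lp, regions$width, regions$start)
  best_i <- ord[1L]
  best <- as.list(enrich_tibble(motif_id, regions[best_i, , drop = FALSE],
                                s[best_i], S, N, lp[best_i], n_tests,
                                n_motifs))
  # gate before building the full table: only candidates that can pass the
  # E-value threshold need materializing
  adj <- adjust_from_log(lp, n_tests)
  pass <- which(motif_evalue(adj$p_adj, n_motifs) <= alpha_evalue)
  tbl <- enrich_tibble(motif_id, regions[pass, , drop = FALSE], s[pass], S, N,
                       lp[pass], n_tests, n_motifs)
  tbl <- select_nonoverlapping(tbl, alpha_evalue = alpha_evalue)
  if (mode == "central" && nrow(tbl) > 1L) {
    tbl <- tbl[1L, , drop = FALSE]
  }
  new_enrich(tbl, motif_id, N, S, mode, n_tests, n_motifs, nrow(regions),
             best = best)
}

enrich_tibble <- function(motif_id, regions, s, S, N, lp, n_tests, n_motifs) {
  adj <- adjust_from_log(lp, n_tests)
  tibble(
    motif_id = rep_len(motif_id, nrow(regions)),
    start = regions$start,
    width = regions$width,
    region_center = regions$start + (regions$width - 1) / 2 - (N - 1) / 2,
    region_width = regions$width,
    s = as.integer(s),
    S = rep_len(as.integer(S), nrow(regions)),
    r = regions$width / N,
    p_raw = exp(lp),
    log_p_raw = lp,
    n_tests = rep_len(as.integer(n_tests), nrow(regions)),
    p_adj = adj$p_adj %||% numeric(0),
    log_p_adj = adj$ln_p_adj %||% numeric(0),
    evalue = motif_evalue(adj$p_adj %||% numeric(0), n_motifs)
  )
}

new_enrich <- function(tbl, motif_id, N, S, mode, n_tests, n_motifs,
                       regions_tested, best) {
  structure(tbl, motif_id = motif_id, N = as.integer(N), S = as.integer(S),
            mode = mode, n_tests = as.integer(n_tests),
            n_motifs = n_motifs, regions_tested = as.integer(regions_tested),
            best = best, class = c("mz_enrich", class(tibble())))
}
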