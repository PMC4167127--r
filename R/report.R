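REPORT_COLUMNS <- c("motif_id", "motif_name", "consensus", "evalue",
                    "adj_pvalue", "log_adj_pvalue", "region_center",
                    "region_width", "sites_in_region", "total_sites",
                    "control_sites_in_region", "control_total_sites",
                    "fisher_adj_pvalue", "fisher_evalue", "odds_ratio")

#' Run the full local / differential local enrichment analysis
#'
#' For every motif: scan the primary set (fixed or optimized score threshold),
#' enumerate and test candidate sub-regions, adjust p-values and compute
#' E-values, greedily select non-overlapping significant sub-regions, and —
#' when a control set is given — test each reported sub-region for
#' differential enrichment with the two-sided Fisher exact test (control
#' scanned at the threshold chosen on the primary set). The per-motif report
#' row describes the motif's best sub-region; its Fisher columns are taken
#' from that sub-region when it passed the significance gate, and otherwise
#' report no differential evidence (adjusted Fisher p-value 1, Fisher E-value
#' at the compendium ceiling).
#'
#' @param primary Primary `mz_seqset` (data-frame-first).
#' @param motifs An `mz_motif_list` (e.g. from [read_meme()]) or single
#'   `mz_motif`.
#' @param control Optional control `mz_seqset` (same sequence length).
#' @param mode `"central"` (default) or `"local"` sub-region enumeration.
#' @param strands `"both"` (default) or `"single"`.
#' @param threshold Fixed score threshold in bits (default 5).
#' @param optimize Optimize the threshold per motif instead
#'   ([optimize_threshold()]); the multiple-test count then includes the
#'   number of thresholds tried.
#' @param min_width,max_width,width_step Sub-region width grid.
#' @param alpha_evalue E-value significance gate for reporting sub-regions
#'   (default 10).
#' @param compendium_size E-value multiplier; defaults to the number of input
#'   motifs, but can be set to the size of the full compendium the motifs
#'   were drawn from.
#' @param bg `"from-data"` (default; estimated over primary + control) or
#'   `"uniform"`, or a numeric vector of 4 frequencies.
#' @param pseudo Pseudocount for log-odds conversion (default 0.1).
#' @param seed Integer seed for the scanning tie-break RNG.
#' @param smooth_bp Odd moving-average window for site probability curves
#'   (default 11).
#' @return An `mz_run` object: list with `report` (one tibble row per motif,
#'   columns as in [write_report()]), `regions` (all reported sub-regions,
#'   with differential statistics when a control was given), `curves`
#'   (per-motif site probability curves), `details` (per-motif scan/threshold
#'   metadata) and `params`.
#' @export
run_enrichment <- function(primary, motifs, control = NULL,
                           mode = c("central", "local"),
                           strands = c("both", "single"), threshold = 5,
                           optimize = FALSE, min_width = 10L,
                           max_width = NULL, width_step = 5L,
                           alpha_evalue = 10, compendium_size = NULL,
                           bg = "from-data", pseudo = 0.1, seed = 1L,
                           smooth_bp = 11L) {
  mode <- arg_match(mode)
  strands <- arg_match(strands)
  motifs <- as_motif_list(motifs)
  stopifnot(is.data.frame(primary))
  if (!is.null(control)) check_same_L(primary, control)
  n_motifs <- compendium_size %||% length(motifs)
  seq_alpha <- attr(primary, "alphabet", exact = TRUE) %||% "ACGT"
  if (any(vapply(motifs, function(m) m$alphabet, "") != seq_alpha)) {
    abort(paste0("motif alphabet does not match the sequence alphabet (",
                 seq_alpha, ")"))
  }
  bgv <- if (is.numeric(bg)) {
    check_background(bg)
  } else if (identical(bg, "uniform")) {
    rep(0.25, 4)
  } else {
    compute_background(c(list(primary), if (!is.null(control)) list(control)))
  }
  L <- seqset_L(primary)

  report_rows <- list()
  region_rows <- list()
  curve_rows <- list()
  details <- list()
  for (m in motifs) {
    det <- list(motif_id = m$id, seed = seed)
    n_thr <- 1L
    if (optimize) {
      opt <- optimize_threshold(primary, m, bg = bgv, strands = strands,
                                seed = seed, mode = mode,
                                min_width = min_width, max_width = max_width,
                                width_step = width_step, pseudo = pseudo)
      if (is.null(opt)) {
        details[[m$id]] <- c(det, list(threshold = NA_real_, S = 0L))
        report_rows[[m$id]] <- empty_report_row(m, n_motifs, !is.null(control))
        next
      }
      scan_p <- opt$scan
      thr <- opt$threshold
      n_thr <- opt$n_thresholds_tested
    } else {
      scan_p <- scan_best_sites(primary, m, bg = bgv, strands = strands,
                                threshold = threshold, seed = seed,
                                pseudo = pseudo)
      thr <- threshold
    }
    scan_c <- if (!is.null(control)) {
      scan_best_sites(control, m, bg = bgv, strands = strands,
                      threshold = thr, seed = seed, pseudo = pseudo)
    } else NULL
    enr <- enrich_local(scan_p, mode = mode, min_width = min_width,
                        max_width = max_width, width_step = width_step,
                        n_motifs = n_motifs, n_threshold_tests = n_thr,
                        alpha_evalue = alpha_evalue)
    det <- c(det, list(threshold = thr, n_thresholds_tested = n_thr,
                       S = nrow(scan_p),
                       S_control = if (!is.null(scan_c)) nrow(scan_c),
                       N = attr(scan_p, "N"),
                       n_tests = attr(enr, "n_tests")))
    diff <- if (!is.null(scan_c)) {
      enrich_differential(enr, scan_p, scan_c, n_motifs = n_motifs)
    } else NULL
    region_rows[[m$id]] <- if (!is.null(diff)) diff else as_tibble(enr)
    report_rows[[m$id]] <- report_row(m, enr, diff, scan_p, scan_c, n_motifs)
    if (nrow(scan_p) > 0L) {
      curve_p <- site_probability_curve(scan_p, smooth_bp = smooth_bp)
      curve <- tibble(motif_id = m$id, offset = curve_p$offset,
                      primary_prob = curve_p$prob,
                      control_prob = NA_real_)
      if (!is.null(scan_c) && nrow(scan_c) > 0L) {
        curve$control_prob <- site_probability_curve(scan_c,
                                                     smooth_bp = smooth_bp)$prob
      }
      curve_rows[[m$id]] <- curve
    }
    details[[m$id]] <- det
  }
  report <- bind_rows(report_rows)
  report <- report[order(report$adj_pvalue, report$motif_id), , drop = FALSE]
  structure(
    list(report = report,
         regions = bind_rows(region_rows),
         curves = bind_rows(curve_rows),
         details = details,
         params = list(mode = mode, strands = strands, threshold = threshold,
                       optimize = optimize, min_width = min_width,
                       max_width = max_width, width_step = width_step,
                       alpha_evalue = alpha_evalue, n_motifs = n_motifs,
                       bg = bgv, pseudo = pseudo, seed = seed, L = L,
                       n_primary = nrow(primary),
                       n_control = if (!is.null(control)) nrow(control),
                       smooth_bp = smooth_bp)),
    class = "mz_run")
}

empty_report_row <- function(m, n_motifs, has_control) {
  tibble(motif_id = m$id, motif_name = m$name, consensus = consensus(m),
         evalue = n_motifs, adj_pvalue = 1, log_adj_pvalue = 0,
         region_center = NA_real_, region_width = NA_integer_,
         sites_in_region = NA_integer_, total_sites = 0L,
         control_sites_in_region = NA_integer_,
         control_total_sites = if (has_control) 0L else NA_integer_,
         fisher_adj_pvalue = if (has_control) 1 else NA_real_,
         fisher_evalue = if (has_control) n_motifs else NA_real_,
         odds_ratio = NA_real_)
}

report_row <- function(m, enr, diff, scan_p, scan_c, n_motifs) {
  best <- attr(enr, "best", exact = TRUE)
  if (is.null(best)) return(empty_report_row(m, n_motifs, !is.null(scan_c)))
  has_control <- !is.null(scan_c)
  selected <- nrow(enr) > 0L
  top <- if (selected) as.list(enr[1L, ]) else best
  fisher <- list(p_adj = NA_real_, evalue = NA_real_, odds = NA_real_,
                 c_in = NA_integer_, c_tot = NA_integer_)
  if (has_control) {
    fisher$c_tot <- nrow(scan_c)
    if (selected && !is.null(diff) && nrow(diff) > 0L) {
      # the diff rows parallel the selected enrichment rows; row 1 is the
      # motif's best sub-region
      fisher$p_adj <- diff$fisher_p_adj[1L]
      fisher$evalue <- diff$fisher_evalue[1L]
      fisher$odds <- diff$odds_ratio[1L]
      fisher$c_in <- diff$c[1L]
    } else {
      # no sub-region passed the enrichment gate: no differential evidence,
      # reported at the E-value ceiling
      fisher$p_adj <- 1
      fisher$evalue <- n_motifs
      fisher$c_in <- count_in_region(scan_c, top$start, top$width)
      t2 <- build_table(scan_p, scan_c, top$start, top$width)
      fisher$odds <- odds_ratio_corrected(t2$a, t2$b, t2$c, t2$d)
    }
  }
  tibble(motif_id = m$id, motif_name = m$name, consensus = consensus(m),
         evalue = top$evalue, adj_pvalue = top$p_adj,
         log_adj_pvalue = top$log_p_adj,
         region_center = top$region_center,
         region_width = as.integer(top$region_width),
         sites_in_region = as.integer(top$s), total_sites = nrow(scan_p),
         control_sites_in_region = fisher$c_in,
         control_total_sites = fisher$c_tot,
         fisher_adj_pvalue = fisher$p_adj, fisher_evalue = fisher$evalue,
         odds_ratio = fisher$odds)
}

#' @export
print.mz_run <- function(x, n = 10, ...) {
  p <- x$params
  cat("<mz_run> ", nrow(x$report), " motif(s), mode=", p$mode,
      ", strands=", p$strands,
      if (p$optimize) ", optimized threshold" else
        paste0(", threshold=", p$threshold, " bits"),
      ", seed=", p$seed, "\n", sep = "")
  cat("primary n=", p$n_primary,
      if (!is.null(p$n_control)) paste0(", control n=", p$n_control),
      ", L=", p$L, " bp, compendium size ", p$n_motifs, "\n", sep = "")
  print(head(x$report, n))
  invisible(x)
}

#' Positional distribution of best sites
#'
#' Histogram of best-site centers (offsets in bp relative to the sequence
#' center), normalized by the number of matched sequences so that the
#' pre-smoothing values sum to 1, then moving-average smoothed with an odd
#' window (zero-padded at the edges).
#'
#' @param scan An `mz_scan` with at least one site.
#' @param smooth_bp Odd smoothing window in bp (default 1 = no smoothing).
#' @return An `mz_curve` tibble: `offset`, `prob_raw` (pre-smoothing),
#'   `prob`.
#' @export
site_probability_curve <- function(scan, smooth_bp = 1L) {
  if (smooth_bp %% 2L != 1L) abort("'smooth_bp' must be odd")
  if (nrow(scan) == 0L) abort("no sites to summarize")
  N <- attr(scan, "N", exact = TRUE)
  L <- attr(scan, "L", exact = TRUE)
  w <- attr(scan, "motif_width", exact = TRUE)
  offsets <- (0:(N - 1)) + (w - 1) / 2 - (L - 1) / 2
  counts <- tabulate(scan$start + 1L, nbins = N)
  prob_raw <- counts / nrow(scan)
  prob <- if (smooth_bp > 1L) {
    k <- as.integer(smooth_bp)
    full <- stats::convolve(prob_raw, rep(1 / k, k), type = "open")
    full[((k - 1L) %/% 2L + 1L):((k - 1L) %/% 2L + N)]
  } else {
    prob_raw
  }
  structure(tibble(offset = offsets, prob_raw = prob_raw, prob = prob),
            motif_id = attr(scan, "motif_id", exact = TRUE),
            smooth_bp = smooth_bp,
            class = c("mz_curve", class(tibble())))
}

#' Expected fraction of sequences containing two uncorrelated motifs
#'
#' Under independence, the expected intersection fraction is the product of
#' the individual fractions (e.g. 34% x 22% = 7.48%).
#'
#' @param frac_a,frac_b Fractions in \[0, 1\].
#' @return `frac_a * frac_b`.
#' @examples
#' expected_intersection(0.34, 0.22)
#' @export
expected_intersection <- function(frac_a, frac_b) {
  if (any(frac_a < 0 | frac_a > 1) || any(frac_b < 0 | frac_b > 1)) {
    abort("fractions must be in [0, 1]")
  }
  frac_a * frac_b
}

#' Observed vs. expected intersection of two motif-containing sequence sets
#'
#' @param ids_a,ids_b Character vectors of sequence ids containing each motif.
#' @param n_total Total number of sequences.
#' @return One-row tibble: `frac_a`, `frac_b`, `expected` (product),
#'   `observed` (intersection fraction).
#' @export
intersection_stats <- function(ids_a, ids_b, n_total) {
  stopifnot(n_total >= 1)
  fa <- length(unique(ids_a)) / n_total
  fb <- length(unique(ids_b)) / n_total
  tibble(frac_a = fa, frac_b = fb,
         expected = expected_intersection(fa, fb),
         observed = length(intersect(ids_a, ids_b)) / n_total)
}

#' Rank of the best motif whose name matches a family substring
#'
#' Case-insensitive substring search over motif names; the rank is the 1-based
#' position of the best match when the report is sorted ascending by the
#' chosen column (ties broken by motif id, stably).
#'
#' @param report A report tibble (from an `mz_run` or [read_report()]).
#' @param substring Family substring, e.g. `"stat"`.
#' @param sort_column `"evalue"`, `"log_adj_pvalue"` or `"fisher_evalue"`.
#' @return One-row tibble: `query`, `motif_id`, `motif_name`, `rank`,
#'   `found`.
#' @export
family_rank <- function(report, substring,
                        sort_column = c("evalue", "log_adj_pvalue", "fisher_evalue")) {
  sort_column <- arg_match(sort_column)
  if (nrow(report) == 0L) abort("empty report")
  ord <- order(report[[sort_column]], report$motif_id)
  sorted <- report[ord, , drop = FALSE]
  hit <- grepl(tolower(substring), tolower(sorted$motif_name), fixed = TRUE)
  if (!any(hit)) {
    return(tibble(query = substring, motif_id = NA_character_,
                  motif_name = NA_character_, rank = NA_integer_,
                  found = FALSE))
  }
  i <- which(hit)[1L]
  tibble(query = substring, motif_id = sorted$motif_id[i],
         motif_name = sorted$motif_name[i], rank = i, found = TRUE)
}

fmt_cell <- function(x) {
  if (is.integer(x)) return(ifelse(is.na(x), "NA", as.character(x)))
  if (is.numeric(x)) {
    out <- ifelse(is.finite(x), sprintf("%.5e", x),
                  ifelse(is.na(x), "NA", as.character(x)))
    return(out)
  }
  ifelse(is.na(x), "NA", as.character(x))
}

#' Write an analysis report to disk
#'
#' Writes `report.tsv` (15 fixed columns, '#'-prefixed header; numbers in
#' 6-significant-digit scientific notation, counts as exact integers),
#' `report.json` (full detail: per-motif sub-regions, thresholds, seeds,
#' multiple-test counts) and `curves.tsv` (per-motif site probability
#' curves).
#'
#' @param run An `mz_run` from [run_enrichment()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(run, dir) {
  stopifnot(inherits(run, "mz_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "report.tsv")
  rep_ <- run$report
  names(rep_) <- REPORT_COLUMNS[match(names(rep_), REPORT_COLUMNS)]
  cells <- vapply(rep_, fmt_cell, character(nrow(rep_)))
  if (nrow(rep_) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste0("#", paste(REPORT_COLUMNS, collapse = "\t")),
             apply(cells, 1L, paste, collapse = "\t"))
  writeLines(lines, tsv)
  json <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(params = run$params[setdiff(names(run$params), "bg")],
         background = as.list(run$params$bg),
         details = run$details,
         regions = run$regions,
         report = run$report),
    json, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  curves <- file.path(dir, "curves.tsv")
  readr::write_tsv(run$curves, curves)
  invisible(c(report_tsv = tsv, report_json = json, curves_tsv = curves))
}

#' Read back a TSV report written by [write_report()]
#' @param path Path to `report.tsv`.
#' @return The report tibble (15 columns).
#' @export
read_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- sub("^#", "", lines[1L])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  if (length(lines) == 1L) {
    body <- lapply(cols, function(x) character(0))
    names(body) <- cols
    out <- as_tibble(body)
  } else {
    out <- readr::read_tsv(I(lines[-1L]), col_names = cols, na = "NA",
                           show_col_types = FALSE)
  }
  int_cols <- c("region_width", "sites_in_region", "total_sites",
                "control_sites_in_region", "control_total_sites")
  for (cc in intersect(int_cols, names(out))) {
    out[[cc]] <- as.integer(out[[cc]])
  }
  out
}
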