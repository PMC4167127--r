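#' Build the 2x2 success/failure x primary/control table for a sub-region
#'
#' Successes are best matches inside the sub-region, failures are best matches
#' outside it, counted separately in the primary and control scans (which must
#' share the same coordinate space `N`).
#'
#' @param primary,control `mz_scan` results for the same motif on two sets.
#' @param start,width Sub-region `[start, start + width)`.
#' @return Named list `a` (primary successes), `b` (primary failures),
#'   `c` (control successes), `d` (control failures).
#' @export
build_table <- function(primary, control, start, width) {
  Np <- attr(primary, "N", exact = TRUE)
  Nc <- attr(control, "N", exact = TRUE)
  if (!is.null(Np) && !is.null(Nc) && Np != Nc) {
    abort("primary and control scans have different N; cannot compare regions")
  }
  a <- count_in_region(primary, start, width)
  c_ <- count_in_region(control, start, width)
  list(a = a, b = nrow(primary) - a, c = c_, d = nrow(control) - c_)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Sums the hypergeometric probabilities (margins fixed) of every table at
#' most as probable as the observed one, with a `1e-7` relative slack for
#' floating-point ties. An all-zero table returns 1 by convention.
#'
#' @param a,b,c,d Cell counts (primary successes/failures, control
#'   successes/failures); alternatively pass a 2x2 matrix or the list from
#'   [build_table()] as `a`.
#' @return The two-sided p-value.
#' @examples
#' fisher_two_sided(2, 0, 0, 2)  # 1/3
#' @export
fisher_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.list(a) && is.null(b)) {
    d <- a$d; c <- a$c; b <- a$b; a <- a$a
  } else if (is.matrix(a) && is.null(b)) {
    d <- a[2, 2]; c <- a[1, 2]; b <- a[2, 1]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("table cells must be non-negative integers")
  }
  if (all(cells == 0)) return(1)
  m <- a + c          # total successes
  n_ <- b + d         # total failures
  k <- a + b          # primary column total
  x <- max(0, k - n_):min(k, m)
  logp <- dhyper(x, m, n_, k, log = TRUE)
  lobs <- dhyper(a, m, n_, k, log = TRUE)
  min(1, sum(exp(logp[logp <= lobs + log1p(1e-7)])))
}

odds_ratio_corrected <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Differential enrichment of reported sub-regions (primary vs. control)
#'
#' For each sub-region where the motif is significantly locally enriched in
#' the primary set, tests whether the proportion of best matches falling
#' inside the sub-region differs between the primary and control sets
#' (two-sided Fisher exact test on the success/failure x primary/control
#' table). Fisher p-values are adjusted with the same multiple-test count `n`
#' as the enrichment p-values and multiplied by the compendium size to give
#' the Fisher E-value; the odds ratio `(a d)/(b c)` (with a +0.5 correction to
#' every cell when any cell is zero) is the effect size.
#'
#' @param enriched An `mz_enrich` tibble of reported sub-regions
#'   (data-frame-first; from [enrich_local()] on the primary scan).
#' @param primary,control `mz_scan` results for the motif on the two sets.
#' @param n_motifs Compendium size (default: the `n_motifs` attribute of
#'   `enriched`).
#' @param n_tests Multiple-test count (default: the enrichment `n_tests`).
#' @return An `mz_diff` tibble: the rows of `enriched` plus `a`, `b`, `c`,
#'   `d`, `fisher_p_raw`, `fisher_p_adj`, `fisher_evalue`, `odds_ratio`.
#' @export
enrich_differential <- function(enriched, primary, control, n_motifs = NULL,
                                n_tests = NULL) {
  stopifnot(is.data.frame(enriched))
  n_motifs <- n_motifs %||% attr(enriched, "n_motifs", exact = TRUE) %||% 1L
  n_tests <- n_tests %||% attr(enriched, "n_tests", exact = TRUE) %||%
    unique(enriched$n_tests)[1L]
  rows <- lapply(seq_len(nrow(enriched)), function(i) {
    t2 <- build_table(primary, control, enriched$start[i], enriched$width[i])
    p <- fisher_two_sided(t2)
    tibble(a = t2$a, b = t2$b, c = t2$c, d = t2$d, fisher_p_raw = p,
           odds_ratio = odds_ratio_corrected(t2$a, t2$b, t2$c, t2$d))
  })
  extra <- if (length(rows)) bind_rows(rows) else {
    tibble(a = integer(0), b = integer(0), c = integer(0), d = integer(0),
           fisher_p_raw = numeric(0), odds_ratio = numeric(0))
  }
  extra$fisher_p_adj <- adjust_pvalue(extra$fisher_p_raw, n_tests)
  extra$fisher_evalue <- motif_evalue(extra$fisher_p_adj, n_motifs)
  out <- as_tibble(cbind(as_tibble(enriched), extra))
  out <- out[, c(names(enriched),
                 c("a", "b", "c", "d", "fisher_p_raw", "fisher_p_adj",
                   "fisher_evalue", "odds_ratio"))]
  structure(out, motif_id = attr(enriched, "motif_id", exact = TRUE),
            n_tests = n_tests, n_motifs = n_motifs,
            class = c("mz_diff", class(tibble())))
}

#' Control-suitability protocol for paired experiments
#'
#' Given the known motif for the assayed factor tested in both directions
#' (set A as primary vs. set B as control, and vice versa), decides which set
#' can safely serve as the control: a direction X-vs-Y with Fisher E-value
#' < 0.05 makes Y unsafe as a control (differential enrichment could be an
#' experiment-efficiency artifact), a Fisher E-value >= 1 makes Y safe, and
#' the interval between is inconclusive. A direction in which the motif has
#' no significantly enriched sub-region at all carries no differential
#' evidence and counts as the E-value ceiling (`n_motifs`).
#'
#' @param a_vs_b,b_vs_a `mz_diff` tibbles for the known motif (or bare Fisher
#'   E-values) for the two directions.
#' @param n_motifs Compendium size used as the ceiling when a direction has
#'   no reported sub-region (default: taken from the inputs).
#' @return A one-row tibble: `evalue_a_vs_b`, `evalue_b_vs_a`,
#'   `b_as_control` and `a_as_control` (each `"safe"`, `"unsafe"` or
#'   `"inconclusive"`), and a combined `verdict` (`"A_safe_as_control"`,
#'   `"B_safe_as_control"`, `"both_safe"`, `"neither_safe"` or
#'   `"inconclusive"`).
#' @export
control_suitability <- function(a_vs_b, b_vs_a, n_motifs = NULL) {
  ev <- function(x) {
    if (is.numeric(x)) return(x[1L])
    stopifnot(is.data.frame(x))
    ceiling_ev <- n_motifs %||% attr(x, "n_motifs", exact = TRUE) %||% 1
    if (nrow(x) == 0L) ceiling_ev else min(x$fisher_evalue)
  }
  e_ab <- ev(a_vs_b)
  e_ba <- ev(b_vs_a)
  judge <- function(e) {
    if (e < 0.05) "unsafe" else if (e >= 1) "safe" else "inconclusive"
  }
  b_ok <- judge(e_ab)  # A vs B speaks to B's suitability as a control
  a_ok <- judge(e_ba)
  verdict <- if (b_ok == "safe" && a_ok == "safe") {
    "both_safe"
  } else if (b_ok == "safe" && a_ok != "safe") {
    "B_safe_as_control"
  } else if (a_ok == "safe" && b_ok != "safe") {
    "A_safe_as_control"
  } else if (b_ok == "unsafe" && a_ok == "unsafe") {
    "neither_safe"
  } else {
    "inconclusive"
  }
  tibble(evalue_a_vs_b = e_ab, evalue_b_vs_a = e_ba,
         b_as_control = b_ok, a_as_control = a_ok, verdict = verdict)
}
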