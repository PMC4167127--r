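#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an analysis run into its per-motif report
#'
#' @param x An `mz_run`.
#' @param ... Unused.
#' @return The report tibble (one row per motif, 15 columns).
#' @export
tidy.mz_run <- function(x, ...) as_tibble(x$report)

#' One-row summary of an analysis run
#'
#' @param x An `mz_run`.
#' @param ... Unused.
#' @return A one-row tibble: run dimensions, mode, threshold policy, seed,
#'   and the number of motifs with E-value below 0.05 and below the
#'   compendium ceiling.
#' @export
glance.mz_run <- function(x, ...) {
  p <- x$params
  tibble(n_motifs = nrow(x$report), compendium_size = p$n_motifs,
         n_primary = p$n_primary,
         n_control = p$n_control %||% NA_integer_, L = p$L,
         mode = p$mode, strands = p$strands,
         optimized_threshold = p$optimize, seed = p$seed,
         n_significant = sum(x$report$evalue < 0.05),
         n_differential = sum(x$report$fisher_evalue < 0.05, na.rm = TRUE))
}

#' Tidy enrichment or differential sub-region tables
#' @param x An `mz_enrich` or `mz_diff`.
#' @param ... Unused.
#' @return A plain tibble of the reported sub-regions.
#' @export
tidy.mz_enrich <- function(x, ...) as_tibble(x)

#' @rdname tidy.mz_enrich
#' @export
tidy.mz_diff <- function(x, ...) as_tibble(x)

#' Best-sub-region summary of a local enrichment analysis
#' @param x An `mz_enrich`.
#' @param ... Unused.
#' @return One-row tibble with the best sub-region's statistics (whether or
#'   not it passed the significance gate) and the analysis dimensions.
#' @export
glance.mz_enrich <- function(x, ...) {
  best <- attr(x, "best", exact = TRUE)
  base <- tibble(motif_id = attr(x, "motif_id", exact = TRUE),
                 S = attr(x, "S", exact = TRUE),
                 N = attr(x, "N", exact = TRUE),
                 mode = attr(x, "mode", exact = TRUE),
                 n_tests = attr(x, "n_tests", exact = TRUE),
                 n_selected = nrow(x))
  if (is.null(best)) {
    base$p_adj <- NA_real_
    base$evalue <- NA_real_
  } else {
    base$p_adj <- best$p_adj
    base$evalue <- best$evalue
    base$best_start <- best$start
    base$best_width <- best$width
  }
  base
}
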