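#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot site probability curves
#'
#' Positional distribution of best motif matches (offset in bp relative to
#' the sequence center), primary as a solid line and control (when present)
#' dotted.
#'
#' @param curves The `curves` tibble of an `mz_run` (columns `motif_id`,
#'   `offset`, `primary_prob`, `control_prob`), or an `mz_curve` from
#'   [site_probability_curve()].
#' @param motifs Optional motif ids to display (default: all present).
#' @return A ggplot object.
#' @export
plot_site_distribution <- function(curves, motifs = NULL) {
  if (inherits(curves, "mz_curve")) {
    curves <- tibble(motif_id = attr(curves, "motif_id", exact = TRUE) %||% "motif",
                     offset = curves$offset, primary_prob = curves$prob,
                     control_prob = NA_real_)
  }
  if (!is.null(motifs)) {
    curves <- curves[curves$motif_id %in% motifs, , drop = FALSE]
  }
  long <- tidyr::pivot_longer(curves, c("primary_prob", "control_prob"),
                              names_to = "set", values_to = "prob")
  long$set <- sub("_prob$", "", long$set)
  long <- long[!is.na(long$prob), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$offset, y = .data$prob,
                                     linetype = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(primary = "solid",
                                              control = "dotted")) +
    ggplot2::facet_wrap(~motif_id, scales = "free_y") +
    ggplot2::labs(x = "offset from sequence center (bp)",
                  y = "site probability", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_site_distribution
#' @param object An `mz_run`.
#' @param ... Passed to [plot_site_distribution()].
#' @export
autoplot.mz_run <- function(object, ...) {
  plot_site_distribution(object$curves, ...)
}

#' @rdname plot_site_distribution
#' @export
autoplot.mz_curve <- function(object, ...) {
  plot_site_distribution(object, ...)
}
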