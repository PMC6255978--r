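#' Degree-distribution histogram per interactome snapshot
#'
#' Degrees are shown on a log10 x-axis, faceted by snapshot — a large
#' fraction of dark genes has low connectivity with a heavy right tail, and
#' the log scale makes the tail visible.
#'
#' @param object A [degree_profile()] result.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.degree_table <- function(object, bins = 20, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$snapshot)) +
    ggplot2::labs(x = "degree (distinct partners)", y = "genes") +
    ggplot2::theme_minimal()
}

#' Evidence-score distribution with tier cutoffs
#'
#' @param object A [score_and_tier()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evidence_summary <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$score, fill = .data$tier)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_brewer(palette = "YlOrRd", drop = FALSE) +
    ggplot2::labs(x = "evidence score S (number of supporting sources)",
                  y = "genes", fill = "tier") +
    ggplot2::theme_minimal()
}

#' Bar chart of Venn region sizes for a consensus result
#'
#' @param consensus A [consensus_sets()] result.
#' @return A ggplot object; regions ordered by how many sets share them.
#' @export
plot_venn_regions <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_result"))
  vr <- consensus$venn_regions
  if (is.null(vr) || nrow(vr) == 0) {
    stop("consensus result has no Venn regions to plot", call. = FALSE)
  }
  vr$region <- factor(vr$region, levels = vr$region[order(vr$n_sets)])
  ggplot2::ggplot(vr, ggplot2::aes(x = .data$region, y = .data$count,
                                   fill = factor(.data$n_sets))) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "regulators in region",
                  fill = "sets sharing") +
    ggplot2::theme_minimal()
}
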