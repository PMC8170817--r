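# ggplot2 views of the result objects.

#' Plot a corrected gene: coverage and dominance along the reference
#'
#' Column depth coloured by dominance class, with correction positions
#' rugged underneath. Useful to spot repeat-contaminated stretches (two/
#' three-type dominance runs) and coverage taper at the flanks.
#'
#' @param object a [correct_reads()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gene_correction <- function(object, ...) {
  prof <- column_profiles(object$array)
  prof$dominance <- factor(prof$dominance, levels = 1:4,
                           labels = paste0(1:4, "-type"))
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$col, y = .data$depth,
                                          colour = .data$dominance)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::labs(
      title = paste0("Alignment array of ", object$ext_ref$gene_id),
      x = "extended reference column (0-based)", y = "column depth",
      colour = "dominance"
    ) +
    ggplot2::theme_minimal()
  if (nrow(object$records) > 0L) {
    p <- p + ggplot2::geom_rug(
      data = dplyr::distinct(object$records, .data$col),
      ggplot2::aes(x = .data$col), inherit.aes = FALSE, sides = "b",
      alpha = 0.4, length = ggplot2::unit(0.02, "npc")
    )
  }
  p
}

#' Plot per-gene precision / recall / gain
#'
#' @param object an `ec_report` from [run_study()].
#' @param ... unused.
#' @return a ggplot (grouped bar chart, percent scale).
#' @export
autoplot.ec_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("gene_id", "precision", "recall", "gain")],
    cols = c("precision", "recall", "gain"),
    names_to = "metric", values_to = "percent"
  )
  long$metric <- factor(long$metric, levels = c("precision", "recall", "gain"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene_id, y = .data$percent,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(min(90, floor(min(long$percent))), 100)) +
    ggplot2::labs(x = NULL, y = "%", fill = NULL) +
    ggplot2::theme_minimal()
}
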