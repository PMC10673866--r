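#' Manhattan-style panel plot of posterior inclusion probabilities
#'
#' One panel per origin class (Control, or Bi/Bt/Bx for an origin fit),
#' position on the x axis and inclusion PIP on the y axis, with an optional
#' threshold line.
#'
#' @param tidy_fit output of [tidy.bayesr_fit()] with `col_info` attached
#'   (columns `chrom`, `pos_bp`, `class`, `pip_inclusion`).
#' @param threshold optional horizontal reference line (default 0.20).
#' @return a ggplot object.
#' @export
plot_pip_manhattan <- function(tidy_fit, threshold = 0.20) {
  need <- c("chrom", "pos_bp", "class", "pip_inclusion")
  if (!all(need %in% names(tidy_fit))) {
    abort("tidy_fit must carry chrom, pos_bp, class, pip_inclusion (pass col_info to tidy())")
  }
  cls <- intersect(c("control", ORIGIN_LEVELS), unique(tidy_fit$class))
  tidy_fit$class <- factor(tidy_fit$class, levels = cls)
  p <- ggplot2::ggplot(tidy_fit,
                       ggplot2::aes(x = .data$pos_bp / 1e6, y = .data$pip_inclusion,
                                    colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$class)) +
    ggplot2::labs(x = "position (Mb)", y = "posterior inclusion probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' @method autoplot bayesr_fit
#' @export
autoplot.bayesr_fit <- function(object, col_info = NULL, threshold = 0.20, ...) {
  td <- tidy(object, col_info = col_info)
  if (is.null(col_info)) {
    td$chrom <- "1"; td$pos_bp <- seq_len(nrow(td)); td$class <- "all"
  }
  plot_pip_manhattan(td, threshold = threshold)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' b-value track along a chromosome for one animal
#'
#' Scatter of per-window b-values (both haplotype copies) against window
#' midpoint, the per-animal view of how origin assignment tiles a
#' chromosome.
#'
#' @param calls an `origin_calls` tibble.
#' @param animal_id the animal to plot.
#' @param chrom optional chromosome filter.
#' @return a ggplot object.
#' @export
plot_bvalues <- function(calls, animal_id, chrom = NULL) {
  d <- calls[calls$animal_id == animal_id, , drop = FALSE]
  if (nrow(d) == 0) abort("animal not found in calls")
  if (!is.null(chrom)) d <- d[d$chrom == chrom, , drop = FALSE]
  long <- tidyr::pivot_longer(as_tibble(d)[c("chrom", "start_bp", "end_bp", "b0", "b1")],
                              cols = c("b0", "b1"), names_to = "copy", values_to = "b")
  long$mid <- (long$start_bp + long$end_bp) / 2
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mid / 1e6, y = .data$b,
                                     shape = .data$copy)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "b-value (P(Bos indicus origin))") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
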