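#' Plot sliding-window statistics along the genome
#'
#' Faceted genome scan: nucleotide diversity per population, FST, Tajima's D
#' per population and (when present) the XP-CLR score, against window
#' midpoint, one panel row per statistic and one column per chromosome.
#'
#' @param ws A window table from [window_stats()] (optionally carrying the
#'   XP-CLR columns).
#' @return A ggplot object.
#' @export
plot_window_stats <- function(ws) {
  value_cols <- intersect(
    c(grep("^(pi|tajd)_", names(ws), value = TRUE), "fst", "xpclr"),
    names(ws))
  long <- tidyr::pivot_longer(
    dplyr::mutate(ws, mid = (.data$start + .data$end) / 2),
    cols = dplyr::all_of(value_cols),
    names_to = "statistic", values_to = "value")
  long$panel <- sub("_(.*)$", "", long$statistic)
  long$population <- ifelse(grepl("_", long$statistic),
                            sub("^[^_]+_", "", long$statistic), "both")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$mid / 1e3, y = .data$value,
                               colour = .data$population)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_grid(panel ~ chrom, scales = "free_y") +
    ggplot2::labs(x = "position (kb)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a folded site frequency spectrum
#'
#' Bars of the observed folded spectrum with the neutral expectation
#' (`1/i + 1/(n-i)`, normalised) overlaid as points.
#'
#' @param sfs Tibble from [folded_sfs()] (a `population` column facets).
#' @param n Number of sampled alleles for the neutral overlay; `NULL`
#'   suppresses the overlay.
#' @return A ggplot object.
#' @export
plot_sfs <- function(sfs, n = NULL) {
  p <- ggplot2::ggplot(sfs, ggplot2::aes(x = .data$minor_count,
                                         y = .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "minor allele count", y = "sites") +
    ggplot2::theme_minimal()
  if ("population" %in% names(sfs)) {
    p <- p + ggplot2::facet_wrap(~population, scales = "free_y")
  }
  if (!is.null(n)) {
    exp_by <- function(total) total * neutral_folded_sfs(n)
    ov <- if ("population" %in% names(sfs)) {
      dplyr::mutate(
        dplyr::group_by(sfs, .data$population),
        expected = exp_by(sum(.data$count)))
    } else dplyr::mutate(sfs, expected = exp_by(sum(.data$count)))
    p <- p + ggplot2::geom_point(data = ov,
                                 ggplot2::aes(y = .data$expected),
                                 colour = "firebrick", size = 1.5)
  }
  p
}

#' Plot LD decay curves
#'
#' Mean genotype r-squared against physical distance, one line per
#' population when the table carries a `population` column.
#'
#' @param ld Tibble from [ld_decay()].
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(ld) {
  aes <- if ("population" %in% names(ld)) {
    ggplot2::aes(x = .data$dist_mid / 1e3, y = .data$mean_r2,
                 colour = .data$population)
  } else {
    ggplot2::aes(x = .data$dist_mid / 1e3, y = .data$mean_r2)
  }
  ggplot2::ggplot(ld, aes) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 1, na.rm = TRUE) +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Genome scan overview of a pipeline run
#'
#' @param object A [run_pipeline()] result.
#' @param ... Unused.
#' @return A ggplot object (the window-statistics scan with called blocks
#'   shaded).
#' @method autoplot sweep_pipeline
#' @export
autoplot.sweep_pipeline <- function(object, ...) {
  p <- plot_window_stats(object$windows)
  if (nrow(object$blocks) > 0) {
    shade <- object$blocks[, c("chrom", "start", "end")]
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start / 1e3, xmax = .data$end / 1e3,
                   ymin = -Inf, ymax = Inf),
      fill = "goldenrod", alpha = 0.25)
  }
  p
}
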