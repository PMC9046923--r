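#' Manhattan plot of per-SNP genetic variance explained
#'
#' @param effects SNP-effect tibble with `chrom`, `pos`, `pct_var`.
#' @param highlight optional marker ids to emphasize (e.g. lead SNPs).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(effects, highlight = NULL) {
  df <- effects %>%
    dplyr::arrange(.data$chrom, .data$pos) %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(chrom_max = max(.data$pos)) %>%
    dplyr::ungroup()
  offsets <- df %>%
    dplyr::distinct(.data$chrom, .data$chrom_max) %>%
    dplyr::mutate(offset = dplyr::lag(cumsum(as.numeric(.data$chrom_max)),
                                      default = 0))
  df <- df %>%
    dplyr::left_join(offsets[, c("chrom", "offset")], by = "chrom") %>%
    dplyr::mutate(x = .data$pos + .data$offset,
                  parity = factor(as.integer(factor(.data$chrom)) %% 2))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$pct_var,
                                        colour = .data$parity)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "genome position", y = "% of genetic variance") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_point(
      data = df[df$marker %in% highlight, ],
      colour = "red", size = 1.6)
  }
  p
}

#' Bar chart of cross-validated accuracy by scenario
#'
#' Mean accuracy per scenario (left) and relative gain over the pedigree
#' baseline (right-style companion available via `gain = TRUE`).
#'
#' @param object a `cv_result` from [run_prediction_cv()].
#' @param gain plot relative gain (%) instead of absolute accuracy.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, gain = FALSE, ...) {
  s <- compare_scenarios(object)
  if (gain) {
    s <- s[s$scenario != "PBLUP", ]
    ggplot2::ggplot(s, ggplot2::aes(x = .data$scenario,
                                    y = .data$relative_gain_pct)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = NULL, y = "relative accuracy gain over PBLUP (%)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(s, ggplot2::aes(x = .data$scenario,
                                    y = .data$mean_accuracy)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = .data$mean_accuracy - .data$sd_accuracy,
        ymax = .data$mean_accuracy + .data$sd_accuracy), width = 0.2) +
      ggplot2::labs(x = NULL, y = "accuracy (r / sqrt(h2))") +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.wssgblup_fit <- function(object, ...) {
  plot_manhattan(object$effects, ...)
}
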