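#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_errorbar facet_wrap labs theme_bw position_dodge
NULL

#' @export
ggplot2::autoplot

#' Plot an extracted ion chromatogram
#'
#' @param object A [extract_xic()] chromatogram.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.chromatogram <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$rt, y = .data$intensity)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(
      x = "Retention time (s)", y = "Intensity",
      title = sprintf("XIC %.4f -> %.4f m/z (%g ppm)",
                      attr(object, "precursor_mz"),
                      attr(object, "product_mz"),
                      attr(object, "ppm_tol"))
    ) +
    theme_bw()
}

#' Marker total-area overview across fractions
#'
#' Replicate total areas per fraction for each panel peptide, with the
#' replicate mean +/- standard error overlaid — the standard visual check
#' of compartment enrichment.
#'
#' @param object An [enrichment_report()].
#' @param ... Unused.
#' @return A ggplot, facetted by peptide.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_report <- function(object, ...) {
  totals <- object$totals |>
    dplyr::filter(!is.na(.data$total_area))
  summ <- totals |>
    dplyr::group_by(.data$gene, .data$peptide, .data$fraction) |>
    dplyr::summarise(
      mean = mean(.data$total_area),
      sem = stats::sd(.data$total_area) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot(summ, aes(x = .data$fraction, y = .data$mean, fill = .data$fraction)) +
    geom_col(alpha = 0.7) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.25) +
    geom_point(data = totals,
               aes(x = .data$fraction, y = .data$total_area), fill = NA,
               shape = 21, size = 1.2) +
    facet_wrap(~ .data$gene + .data$peptide, scales = "free_y") +
    labs(x = "Fraction", y = "Total area (intensity · s)",
         title = "Marker peptide total areas by subcellular fraction") +
    theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' Enrichment-ratio dot plot
#'
#' @param report An [enrichment_report()].
#' @param pairs Fraction pairs to show, as `"N/C"`-style strings
#'   (default the six ordered pairs of C, M and N).
#' @return A ggplot.
#' @export
plot_enrichment_ratios <- function(report,
                                   pairs = c("N/C", "N/M", "M/C", "M/N",
                                             "C/M", "C/N")) {
  ratios <- report$ratios |>
    dplyr::mutate(pair = paste(.data$numerator, .data$denominator, sep = "/")) |>
    dplyr::filter(.data$pair %in% pairs, is.finite(.data$er))
  ggplot(ratios, aes(x = .data$pair, y = .data$er, colour = .data$compartment)) +
    geom_point(position = position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    labs(x = "Fraction pair", y = "Enrichment ratio (log scale)",
         title = "Marker enrichment ratios between fractions") +
    theme_bw()
}
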