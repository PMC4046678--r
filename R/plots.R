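#' Plot an ordered linkage map
#'
#' Marker positions per linkage group, one facetless column per group,
#' with framework (LOD3) markers emphasised.
#'
#' @param object A `pearl_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pearl_map <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$lg), y = .data$cm_sexavg)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$tier == "LOD3"), size = 1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey60"),
                                 labels = c(`TRUE` = "framework", `FALSE` = "placed"),
                                 name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "linkage group", y = "position (Kosambi cM)")
}

#' Cumulative female vs male standardised positions
#'
#' The heterochiasmy profile: cumulative standardised female position
#' against cumulative standardised male position per linkage group, with
#' the 1:1 diagonal. Male centromeric suppression shows as a flat middle
#' segment; telomeric inflation as steep outer segments.
#'
#' @param intervals Output of [standardized_intervals()].
#' @return A ggplot.
#' @export
plot_sex_intervals <- function(intervals) {
  ggplot2::ggplot(intervals,
                  ggplot2::aes(x = .data$cum_std_female, y = .data$cum_std_male)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~lg) +
    ggplot2::labs(x = "female position (% of LG)", y = "male position (% of LG)")
}

#' LD decay over map distance
#'
#' @param decay The `decay` tibble from [decay_table()].
#' @return A ggplot of mean r2 and D' per distance bin.
#' @export
plot_ld_decay <- function(decay) {
  d <- decay |>
    dplyr::mutate(bin = factor(.data$bin, levels = .data$bin)) |>
    tidyr::pivot_longer(c("r2_mean", "dprime_mean"),
                        names_to = "measure", values_to = "mean_ld")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$mean_ld,
                                  group = .data$measure, colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_discrete(labels = c(dprime_mean = "D'", r2_mean = expression(r^2))) +
    ggplot2::labs(x = "map distance (cM)", y = "mean LD", colour = NULL)
}
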