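#' Plot divergence-timing calls
#'
#' Sample-level shared clonal fractions coloured by the early/late label;
#' one bar per metastasis sample.
#'
#' @param object A `met_timing` tibble (possibly row-bound over cases).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.met_timing <- function(object, ...) {
  df <- dplyr::filter(object, .data$level == "sample", !is.na(.data$label))
  ggplot2::ggplot(df, ggplot2::aes(
    x = paste(.data$case_id, .data$target_id, sep = ":"),
    y = .data$shared_clonal_fraction, fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "shared clonal mutation fraction",
                  fill = "divergence") +
    ggplot2::theme_minimal()
}

#' Plot the downsampling curve
#'
#' Mean shared clonal fraction against the number of primary regions used,
#' one line per case; the drop towards small k visualises the illusion of
#' clonality under sparse sampling.
#'
#' @param object A `met_downsample` tibble (possibly row-bound over cases).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.met_downsample <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k_regions,
                                       y = .data$mean_shared_fraction,
                                       group = .data$case_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label_at_k)) +
    ggplot2::labs(x = "primary regions sampled (k)",
                  y = "mean shared clonal fraction",
                  colour = "label at k") +
    ggplot2::theme_minimal()
}

#' Plot cluster dispersion against maximum regional CCF
#'
#' The plane in which subclonal expansions stand out: dominant (high max
#' CCF) and widely spread (high dispersion) clusters sit top-right.
#'
#' @param object A `met_dispersion` tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.met_dispersion <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$dispersion)),
                  ggplot2::aes(x = .data$max_ccf, y = .data$dispersion)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "maximum CCF across primary regions",
                  y = "clonal dispersion index") +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot the simulated early-fraction-versus-size curve
#'
#' @param object A `met_sim_experiment` tibble from
#'   [run_timing_experiment()].
#' @param ... Ignored.
#' @return A ggplot with a log-scaled diameter axis.
#' @export
autoplot.met_sim_experiment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$diameter_mm,
                                       y = .data$fraction_early)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "primary diameter at divergence (mm)",
                  y = "fraction of pairs diverging early") +
    ggplot2::theme_minimal()
}
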