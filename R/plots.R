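#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_segment geom_col
#'   geom_line geom_point scale_fill_viridis_c labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a site-profile heatmap
#'
#' P1 position against time point, filled by relative cut frequency.
#'
#' @param object A [relative_cut_frequency()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.site_profiles <- function(object, ...) {
  ggplot(as_tibble(object), aes(
    x = factor(.data$time_s), y = .data$p1, fill = .data$frequency
  )) +
    geom_tile() +
    scale_fill_viridis_c(name = "Rel. freq. cuts") +
    labs(x = "Time (s)", y = "P1 residue") +
    theme_minimal()
}

#' Plot fragment coverage bars
#'
#' The fragment overview: one horizontal bar per gapless fragment, one row per
#' time point.
#'
#' @param object A [group_fragments()] or [fragment_maps()] result (with a
#'   `time_s` column).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fragment_map <- function(object, ...) {
  d <- as_tibble(object)
  if (!"time_s" %in% names(d)) d$time_s <- 0
  ggplot(d, aes(
    x = .data$start, xend = .data$end,
    y = factor(.data$time_s), yend = factor(.data$time_s)
  )) +
    geom_segment(linewidth = 4) +
    labs(x = "Substrate position", y = "Time (s)") +
    theme_minimal()
}

#' Plot a specificity matrix
#'
#' Amino-acid percentage per window position around the scissile bond.
#'
#' @param object An [aa_distribution()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.specificity_matrix <- function(object, ...) {
  ggplot(as_tibble(object), aes(
    x = .data$position, y = .data$residue, fill = .data$percentage
  )) +
    geom_tile() +
    scale_fill_viridis_c(name = "%") +
    labs(x = "Position", y = "Residue") +
    theme_minimal()
}

#' Plot a fragmentation timeline
#'
#' Interval sets after each ranked cleavage event.
#'
#' @param object A [fragment_timeline()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fragment_timeline <- function(object, ...) {
  ggplot(as_tibble(object), aes(
    x = .data$start, xend = .data$end,
    y = .data$step, yend = .data$step
  )) +
    geom_segment(linewidth = 3) +
    labs(x = "Substrate position", y = "Event step") +
    theme_minimal()
}
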