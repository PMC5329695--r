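# ggplot2 displays. Plots are never load-bearing for the analysis; every
# figure reads straight off a tidy result table.

#' Stacked-bar composition profile
#'
#' Per-position base composition in the E. coli frame, with the same colour
#' encoding used for terminal-region 16S composition figures (blue A, red
#' T/U, green G, purple C, black gap).
#'
#' @param object A [composition_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot composition_profile
#' @export
autoplot.composition_profile <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(cols = c("A", "C", "G", "T", "gap"),
                        names_to = "base", values_to = "count") |>
    dplyr::mutate(base = factor(.data$base, c("A", "T", "G", "C", "gap")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ecoli_pos, y = .data$count,
                                     fill = .data$base)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(A = "#2166ac", T = "#b2182b",
                                          G = "#1a9850", C = "#762a83",
                                          gap = "black")) +
    ggplot2::labs(x = "position (E. coli numbering)", y = "templates",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Coverage-rate bar chart
#'
#' @param object A [coverage_rate()] result tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_coverage <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group, y = .data$coverage_rate,
                               fill = .data$primer_name)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "coverage rate", fill = "primer") +
    ggplot2::theme_minimal()
}

#' Stacked composition of clone libraries
#'
#' @param object A [summarize_clones()] result.
#' @param category Which composition to show: `"origin"` or `"pair"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot clone_summary
#' @export
autoplot.clone_summary <- function(object, category = c("origin", "pair"),
                                   ...) {
  category <- match.arg(category)
  d <- object[object$category == category & object$count > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$library, y = .data$count,
                                  fill = .data$level)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "share of clones",
                  fill = if (category == "origin") "origin" else "19-916 pair") +
    ggplot2::theme_minimal()
}
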