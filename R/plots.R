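#' Heatmap of an ELISpot reactivity table with positivity calls
#'
#' Tiles clones by target animals, filled by spot count on a log1p scale,
#' with positive wells outlined — the binary reactivity pattern each clone
#' presents against the panel.
#'
#' @param reactivity A long reactivity tibble ([read_reactivity()]).
#' @param params A [positivity_params()] object.
#' @return A ggplot object.
#' @export
plot_reactivity <- function(reactivity, params = positivity_params()) {
  called <- call_reactivity(reactivity, params)
  ggplot2::ggplot(called, ggplot2::aes(x = .data$target_id, y = .data$clone_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = log1p(.data$sfc)), colour = "grey85") +
    ggplot2::geom_point(data = dplyr::filter(called, .data$positive),
                        shape = 3, size = 1.6, colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "log1p(SFC)") +
    ggplot2::labs(x = "target animal", y = "T cell clone",
                  subtitle = "crosses mark wells called positive") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Segregation-score plot for a candidate screen
#'
#' Top-ranked candidates per clone, score on the y axis, coloured by
#' exclusivity class; the causal variant of a well-powered screen stands
#' out as the per-clone PERFECT maximum.
#'
#' @param object A `mhag_screen` object ([screen_candidates()]).
#' @param top_n Candidates shown per clone (default 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mhag_screen <- function(object, top_n = 5, ...) {
  shown <- dplyr::filter(object$candidates, .data$rank <= top_n)
  ggplot2::ggplot(shown, ggplot2::aes(x = .data$rank, y = .data$score,
                                      colour = .data$exclusivity)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = .data$clone_id),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$clone_id)) +
    ggplot2::scale_colour_manual(values = c(
      PERFECT = "#1b7837", EXCLUSIVE = "#762a83", NON_EXCLUSIVE = "grey50"
    )) +
    ggplot2::labs(x = "candidate rank", y = "segregation score") +
    ggplot2::theme_minimal()
}

#' Carrier-frequency bar plot
#'
#' @param frequency Output of [carrier_frequency()].
#' @param top_n Sites shown, ordered by carrier percentage (default 20).
#' @return A ggplot object.
#' @export
plot_carrier_frequency <- function(frequency, top_n = 20) {
  shown <- frequency |>
    dplyr::arrange(dplyr::desc(.data$carrier_pct)) |>
    utils::head(top_n)
  ggplot2::ggplot(shown, ggplot2::aes(
    x = stats::reorder(.data$site_id, .data$carrier_pct),
    y = .data$carrier_pct
  )) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "carrier frequency (%)") +
    ggplot2::theme_minimal()
}
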