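#' Bar chart of called event types
#'
#' @param events Events tibble.
#' @return A ggplot object.
#' @export
plot_event_types <- function(events) {
  counts <- dplyr::count(events, .data$event_type)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$event_type, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "event type", y = "events",
                  title = "Alternative splicing events by type") +
    ggplot2::theme_minimal()
}

#' PSI distributions per condition
#'
#' @param psi PSI tibble from [compute_psi()].
#' @param event_ids Optional subset of events to show.
#' @return A ggplot object.
#' @export
plot_psi <- function(psi, event_ids = NULL) {
  if (!is.null(event_ids)) {
    psi <- dplyr::filter(psi, .data$event_id %in% event_ids)
  }
  ggplot2::ggplot(psi, ggplot2::aes(x = .data$condition, y = .data$psi)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~event_id) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "percent spliced in") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential splicing results
#'
#' @param diff Results tibble from [diff_splice()].
#' @param q_cutoff Significance threshold to highlight (default 0.05).
#' @return A ggplot object.
#' @export
plot_diff_splice <- function(diff, q_cutoff = 0.05) {
  d <- diff |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::mutate(significant = .data$q_value < q_cutoff)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_psi,
                                  y = -log10(.data$p_value),
                                  color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(Delta * PSI), y = expression(-log[10](p)),
                  color = paste0("q < ", q_cutoff)) +
    ggplot2::theme_minimal()
}
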