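#' Plot a dated paralog-pair table
#'
#' Ks (and the implied age) of each pair, coloured by duplication
#' mechanism — the standard view of when each mechanism was active.
#'
#' @param pairs A `pf_pairs` tibble from [date_pair_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pf_pairs
#' @export
autoplot.pf_pairs <- function(pairs, ...) {
  df <- as_tibble(pairs) |> filter(!is.na(.data$t_mya))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_mya,
                                   y = stats::reorder(paste(.data$gene_a, .data$gene_b,
                                                            sep = "/"), .data$t_mya),
                                   colour = .data$mechanism)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Duplication age (Myr)", y = NULL,
                  colour = "Mechanism") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pf_pairs
#' @export
plot_pair_ages <- autoplot.pf_pairs

#' Plot per-ancestor gains and losses from a reconciliation
#'
#' @param object A `pf_recon` or the tibble from [ancestral_counts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pf_recon
#' @export
autoplot.pf_recon <- function(object, ...) {
  df <- tidy(object)
  plot_gain_loss(df)
}

#' @rdname autoplot.pf_recon
#' @param counts Tibble with `species_node`, `gains`, `losses` (and
#'   optionally `count`).
#' @export
plot_gain_loss <- function(counts, ...) {
  df <- counts |>
    tidyr::pivot_longer(dplyr::any_of(c("gains", "losses")),
                        names_to = "event", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species_node, y = .data$n,
                                   fill = .data$event)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Species-tree node", y = "Events", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot relative qPCR expression with significance stars
#'
#' @param object A `pf_rq` tibble after [call_regulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pf_rq
#' @export
autoplot.pf_rq <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$rq)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rq_lo, ymax = .data$rq_hi),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~gene) +
    ggplot2::labs(x = NULL, y = expression(2^{-Delta*Delta*Ct})) +
    ggplot2::theme_minimal()
  if ("stars" %in% names(df)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$stars,
                                             y = .data$rq_hi), vjust = -0.3)
  }
  p
}

#' @rdname autoplot.pf_rq
#' @param rq A `pf_rq` tibble.
#' @export
plot_relative_expression <- function(rq, ...) autoplot.pf_rq(rq, ...)
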