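#' Dot-plot of chains
#'
#' Draws each chain as a segment in query-by-reference coordinate space,
#' faceted by sequence pair and coloured by strand — the same picture an
#' external dot-plot viewer would draw from the exported PAF.
#'
#' @param chains Chain tibble.
#' @return A ggplot object.
#' @export
plot_chains <- function(chains) {
  ggplot2::ggplot(chains) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$r_start / 1e6,
      xend = .data$r_end / 1e6,
      y = ifelse(.data$strand == "+", .data$q_start, .data$q_end) / 1e6,
      yend = ifelse(.data$strand == "+", .data$q_end, .data$q_start) / 1e6,
      colour = .data$strand), linewidth = 0.8) +
    ggplot2::facet_grid(q_id ~ r_id) +
    ggplot2::scale_colour_manual(values = c(`+` = "grey30", `-` = "#e66101")) +
    ggplot2::labs(x = "reference (Mb)", y = "query (Mb)", colour = "strand") +
    ggplot2::theme_bw()
}

#' Plot structural-variant calls along reference chromosomes
#'
#' @param svs SV-call tibble from [call_svs()].
#' @return A ggplot object; syntenic blocks grey, inversions orange,
#'   translocations green, duplications blue (the conventional palette of
#'   whole-genome synteny plots).
#' @export
plot_svs <- function(svs) {
  pal <- c(SYN = "grey70", INV = "#e66101", TRL = "#1b9e77", DUP = "#2c7fb8",
           INVDP = "#253494", INVTL = "#66c2a4")
  ggplot2::ggplot(svs) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$r_start / 1e6, xmax = .data$r_end / 1e6,
      ymin = 0, ymax = 1, fill = .data$type)) +
    ggplot2::facet_grid(r_id ~ .) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::labs(x = "reference position (Mb)", y = NULL, fill = "call") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

#' @export
autoplot.pseudochrom_set <- function(object, ...) {
  pl <- object$placements[object$placements$status == "placed", ]
  ggplot2::ggplot(pl) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$r_start / 1e6, xend = .data$r_end / 1e6,
      y = .data$scaffold, yend = .data$scaffold,
      colour = .data$orientation), linewidth = 2) +
    ggplot2::facet_grid(r_id ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "reference position (Mb)", y = "scaffold",
                  colour = "orientation") +
    ggplot2::theme_bw()
}

#' @export
autoplot.bias_report <- function(object, ...) {
  plot_svs(tidy(object) |> filter(.data$source %in% c("anchored_a", "anchored_b"))) +
    ggplot2::facet_grid(r_id ~ source)
}
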