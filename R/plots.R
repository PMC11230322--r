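#' Volcano plot of a specification family
#'
#' Hazard ratio (log scale) against two-sided p (-log10) for every fitted
#' specification, faceted by stratum and exposure form.
#'
#' @param x A `pdi_report` or its `volcano` tibble.
#' @return A ggplot object.
#' @export
plot_volcano <- function(x) {
  tbl <- if (inherits(x, "pdi_report")) x$volcano else x
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$hr, y = -log10(.data$p),
                                    colour = .data$index)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 3,
                        linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(form ~ stratum) +
    ggplot2::labs(x = "hazard ratio", y = expression(-log[10](p)),
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' Violin plot of hazard-ratio distributions by coding direction
#'
#' One violin per food group and scoring direction, as in the agnostic
#' permutation display.
#'
#' @param x A `pdi_report` or its `distribution` tibble.
#' @param stratum Stratum to display.
#' @return A ggplot object.
#' @export
plot_hr_violin <- function(x, stratum = "combined") {
  tbl <- if (inherits(x, "pdi_report")) x$distribution else x
  tbl <- tbl[tbl$stratum == stratum, ]
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$group, y = .data$hr,
                                    fill = .data$direction)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8),
                         linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "hazard ratio", fill = "coding") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Empirical CDFs of hazard ratios by coding direction
#'
#' @param x A `pdi_report` or its `ecdf` tibble.
#' @param stratum Stratum to display.
#' @return A ggplot object.
#' @export
plot_hr_ecdf <- function(x, stratum = "combined") {
  tbl <- if (inherits(x, "pdi_report")) x$ecdf else x
  tbl <- tbl[tbl$stratum == stratum, ]
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$hr, y = .data$cum_frac,
                                    colour = .data$direction)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "hazard ratio", y = "cumulative fraction",
                  colour = "coding") +
    ggplot2::theme_bw()
}
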