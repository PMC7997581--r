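#' Plot an alignment ranking
#'
#' Ranked \eqn{MAE_{\Delta\Delta\delta}} values, best alignment highlighted;
#' the visual gap between the first and second scheme is the margin of the
#' assignment.
#'
#' @param object An `alignment_ranking`.
#' @param top Show at most this many schemes (all 24 of a tetrad fit
#'   comfortably).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.alignment_ranking <- function(object, top = 24, ...) {
  d <- utils::head(tidy(object), top)
  d$alignment <- factor(d$alignment, levels = rev(d$alignment))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mae_dddelta, y = .data$alignment)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$mae_dddelta,
                                       yend = .data$alignment),
                          colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$rank == 1), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::labs(x = expression(MAE[Delta * Delta * delta] ~ "(ppm)"),
                  y = "alignment (experimental ids in calculated order)",
                  title = "Comparison-alignment ranking") +
    ggplot2::theme_minimal()
}

#' Plot a classic per-set score matrix
#'
#' Heat map of the experimental-by-calculated score matrix with the
#' per-experimental-set best candidate outlined; duplicated winners across
#' rows make the ambiguity of the one-vs-one ranking visible.
#'
#' @param object A `classic_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.classic_ranking <- function(object, ...) {
  d <- object$scores
  d$calc_id <- factor(d$calc_id, levels = object$calc_ids)
  d$exp_id <- factor(d$exp_id, levels = rev(object$exp_ids))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$calc_id, y = .data$exp_id,
                                  fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = d[d$best, ], fill = NA, colour = "#c0392b",
                       linewidth = 1) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$score)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "#ffffff", high = "#5dade2",
                                 name = object$metric) +
    ggplot2::labs(x = "calculated set", y = "experimental set",
                  title = sprintf("Classic per-set comparison (%s)", object$metric)) +
    ggplot2::theme_minimal()
}

#' Line plot of shift sets across the carbon skeleton
#'
#' One line per set over the atom index, the standard way to eyeball how
#' similar a group of isomer shift sets is.
#'
#' @param x A `shift_tbl`.
#' @return A ggplot object.
#' @export
plot_shift_sets <- function(x) {
  long <- tidyr::pivot_longer(as_tibble(x), cols = all_of(set_ids(x)),
                              names_to = "set_id", values_to = "shift")
  long$label <- factor(long$label, levels = x$label)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$shift,
                                     colour = .data$set_id,
                                     group = .data$set_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "carbon", y = expression(delta ~ "(ppm)"), colour = "set") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
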