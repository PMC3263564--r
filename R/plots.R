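#' Forest-style plot of a scan result
#'
#' Odds ratios with confidence intervals for every (locus, partition cell)
#' on a log scale; detected rows are filled. Degenerate or infinite rows
#' are dropped from the panel.
#'
#' @param object A `scan_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(is.finite(.data$odds_ratio), .data$odds_ratio > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio, y = .data$cell,
                                   colour = .data$mode,
                                   shape = .data$detected)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~locus) +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL,
                  shape = "detected") +
    ggplot2::theme_minimal()
}

#' Bar plot of a power comparison
#'
#' Detection probability per analysis mode with approximate 95% Monte
#' Carlo error bars.
#'
#' @param object A `power_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_report
#' @export
autoplot.power_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$power)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$power - 1.96 * .data$mc_se),
      ymax = pmin(1, .data$power + 1.96 * .data$mc_se)), width = 0.15) +
    ggplot2::geom_hline(yintercept = df$alpha[1], linetype = 2,
                        colour = "grey40") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "detection probability") +
    ggplot2::theme_minimal()
}

#' Profile plot of per-residue propensity scores
#'
#' @param object A `propensity_profile`.
#' @param threshold Optional horizontal threshold line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot propensity_profile
#' @export
autoplot.propensity_profile <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(unclass_keep(object)),
                       ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "residue position",
                  y = paste0("propensity (", attr(object, "scale_name"),
                             ", window ", attr(object, "window"), ")")) +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 colour = "firebrick")
  p
}

#' Two-track plot of a peptide scan report
#'
#' B- and T-cell score tracks with called antigenic segments shaded.
#'
#' @param object A `pepscan_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pepscan_report
#' @export
autoplot.pepscan_report <- function(object, ...) {
  df <- tibble::as_tibble(unclass_keep(object)) |>
    tidyr::pivot_longer(c("b_score", "t_score"), names_to = "track",
                        values_to = "score") |>
    dplyr::mutate(track = ifelse(.data$track == "b_score", "B cell", "T cell"))
  seg <- dplyr::bind_rows(attr(object, "b_segments"),
                          attr(object, "t_segments")) |>
    dplyr::mutate(track = ifelse(.data$kind == "b_cell", "B cell", "T cell"))
  th <- attr(object, "thresholds")
  thdf <- tibble::tibble(track = c("B cell", "T cell"),
                         threshold = unname(th))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$score))
  if (nrow(seg))
    p <- p + ggplot2::geom_rect(
      data = seg, inherit.aes = FALSE, alpha = 0.2, fill = "orange",
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                   ymin = -Inf, ymax = Inf))
  p +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = thdf,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = 2, colour = "firebrick") +
    ggplot2::facet_wrap(~track, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "residue position", y = "antigenicity index") +
    ggplot2::theme_minimal()
}
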