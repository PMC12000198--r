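# Figure builders. Every plot draws from a tidy table the caller can also
# write out, so no number exists only inside an image.

#' Density plot of observed scores for two groups
#'
#' @param scores A score table holding both groups (e.g. two
#'   [sample_scores()] results bound together), with `group` and `observed`
#'   columns; `value` selects which column is drawn.
#' @param window Optional selection window to shade.
#' @param value Column to plot (`"observed"` or `"true"`).
#' @return A ggplot object.
#' @export
plot_score_densities <- function(scores, window = NULL, value = "observed") {
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data[[value]],
                                            fill = .data$group,
                                            colour = .data$group)) +
    ggplot2::geom_density(alpha = 0.3) +
    ggplot2::labs(x = paste(value, "score"), y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    w <- as_window(window)
    p <- p + ggplot2::annotate(
      "rect",
      xmin = max(w$lower, min(scores[[value]])),
      xmax = min(w$upper, max(scores[[value]])),
      ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p
}

#' Iso-probability contours of true versus observed scores
#'
#' Contour plot of the joint density of (true, observed) scores for one or
#' more populations, the picture in which low reliability shows up as
#' vertical spread around the identity diagonal.
#'
#' @param pops A list of [ctt_population()] objects.
#' @param grid_n Grid resolution per axis.
#' @param span Number of observed-score SDs covered around the means.
#' @return A ggplot object; the underlying grid is in the `data` slot.
#' @export
plot_iso_probability <- function(pops, grid_n = 101, span = 3.5) {
  if (inherits(pops, "ctt_population")) pops <- list(pops)
  df <- purrr::map_dfr(pops, function(pop) {
    sd_x <- sqrt(pop$sigma_t^2 + pop$sigma_e^2)
    t_axis <- seq(pop$mu_g - span * pop$sigma_t, pop$mu_g + span * pop$sigma_t,
                  length.out = grid_n)
    x_axis <- seq(pop$mu_g - span * sd_x, pop$mu_g + span * sd_x,
                  length.out = grid_n)
    tidyr::expand_grid(true = t_axis, observed = x_axis) |>
      dplyr::mutate(density = iso_density(pop, .data$true, .data$observed),
                    group = pop$label)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$true,
                                   z = .data$density, colour = .data$group)) +
    ggplot2::geom_contour(bins = 8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::labs(x = "observed score", y = "true score") +
    ggplot2::theme_minimal()
}

#' Miss-CR gap curves against measurement-error SD
#'
#' @param curves Output of [gap_curve()] (rows may cover several `mu_old`,
#'   `sd_old` and `criterion` settings).
#' @return A ggplot object faceted by `sd_old` and `criterion`.
#' @export
plot_gap_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$sd_error, y = .data$gap,
                                       colour = factor(.data$mu_old))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$sd_old),
                        cols = ggplot2::vars(.data$criterion),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "error SD", y = "miss - CR true-strength gap",
                  colour = "mu (old)") +
    ggplot2::theme_minimal()
}

#' Zero-error gap curves against the decision criterion
#'
#' @param curves Output of [skewness_gap_curve()].
#' @return A ggplot object, one curve per d'.
#' @export
plot_skewness_gap_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$criterion, y = .data$gap,
                                       colour = .data$d_prime,
                                       group = .data$d_prime)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_gradient(low = "#08306b", high = "#9ecae1") +
    ggplot2::labs(x = "decision criterion C", y = "miss - CR true-strength gap",
                  colour = "d'") +
    ggplot2::theme_minimal()
}

#' Strip plot of per-participant 2AFC accuracies
#'
#' @param accuracy Output of [afc_accuracy()].
#' @param min_critical_trials Participants below this rating-1 trial count
#'   are dropped from the rating-1 column.
#' @return A ggplot object.
#' @export
plot_afc_accuracy <- function(accuracy, min_critical_trials = 3L) {
  df <- dplyr::bind_rows(
    dplyr::transmute(accuracy, subset = "overall", acc = .data$overall_acc),
    accuracy |>
      dplyr::filter(.data$n_rating1 >= min_critical_trials) |>
      dplyr::transmute(subset = "rating-1 pairs", acc = .data$rating1_acc)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subset, y = .data$acc)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "accuracy (old word chosen)") +
    ggplot2::theme_minimal()
}
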