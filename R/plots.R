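#' Plot a session's learning curve with its exponential fit
#'
#' @param x An `ll_expfit`.
#' @param errors The per-trial errors the fit was computed from (optional;
#'   defaults to plotting the fitted curve alone).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ll_expfit
#' @export
autoplot.ll_expfit <- function(x, errors = NULL, ...) {
  p <- ggplot2::ggplot(augment(x), ggplot2::aes(x = .data$trial))
  if (!is.null(errors)) {
    p <- p + ggplot2::geom_point(
      data = tibble(trial = x$trials, error = errors),
      ggplot2::aes(y = .data$error), alpha = 0.4, size = 1
    )
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "grey40",
                       linetype = "dashed", linewidth = 0.8) +
    ggplot2::labs(x = "Trial", y = "Movement error (mm)",
                  title = sprintf("a = %.1f, b = %.3f, c = %.1f (R² = %.2f)",
                                  x$a, x$b, x$c, x$r2)) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of scenario totals
#'
#' Expected reward (as a z-score) of every admissible target-selection
#' scenario against its descending rank, with an optional marker for a
#' particular scenario (e.g. a participant's actual choices).
#'
#' @param x An `ll_scenario_dist`.
#' @param highlight_points Optional point total to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ll_scenario_dist
#' @export
autoplot.ll_scenario_dist <- function(x, highlight_points = NULL, ...) {
  h <- dplyr::arrange(x$histogram, dplyr::desc(.data$total))
  h$rank_hi <- cumsum(h$n_scenarios)
  h$zscore <- (h$total - x$mean) / x$sd
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$rank_hi / x$n_total * 100,
                                       y = .data$zscore)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Scenario rank (% of all scenarios)",
                  y = "Expected reward (z-score)") +
    ggplot2::theme_minimal()
  if (!is.null(highlight_points)) {
    r <- scenario_rank(x, highlight_points)
    p <- p + ggplot2::annotate("point", x = r$rank / x$n_total * 100,
                               y = r$zscore, colour = "red", size = 2)
  }
  p
}

#' Plot a fitted choice sequence against the observed one
#'
#' @param x An `ll_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ll_fit
#' @export
autoplot.ll_fit <- function(x, ...) {
  d <- augment(x) |>
    tidyr::pivot_longer(c("observed", "predicted"), names_to = "series",
                        values_to = "target")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$decision, y = .data$target,
                                  colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = 1:6) +
    ggplot2::labs(x = "Decision point", y = "Target index",
                  title = sprintf("%s model: lead %d, lag %d (MAD %.2f)",
                                  x$mode, x$policy$lead, x$policy$lag,
                                  x$mad)) +
    ggplot2::theme_minimal()
}

#' Moving-window bias and variability profiles
#'
#' Four-panel style summary of [moving_bias_variance()] output: windowed
#' mean and SD of the x and y endpoint components across trials.
#'
#' @param bv Tibble from [moving_bias_variance()].
#' @return A ggplot.
#' @export
plot_bias_variance <- function(bv) {
  d <- bv |>
    tidyr::pivot_longer(-"center_trial", names_to = "measure") |>
    dplyr::filter(!startsWith(.data$measure, "bias_fraction"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$center_trial, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$measure, scales = "free_y") +
    ggplot2::labs(x = "Trial (window centre)", y = "mm") +
    ggplot2::theme_minimal()
}

#' Expected-reward lines across horizons for one participant
#'
#' @param points One participant's rows of the `points` table from
#'   [run_exp2()] (columns `horizon`, `slope`, `intercept`, `hit_value`).
#' @param cfg [exp2_config()].
#' @return A ggplot.
#' @export
plot_reward_lines <- function(points, cfg = exp2_config()) {
  rng <- cfg$hit_value_range
  lines <- points |>
    tidyr::expand_grid(v = seq(rng[1], rng[2])) |>
    dplyr::mutate(reward = .data$slope * .data$v + .data$intercept)
  sel <- dplyr::mutate(points,
                       reward = .data$slope * .data$hit_value +
                         .data$intercept)
  ggplot2::ggplot(lines, ggplot2::aes(x = .data$v, y = .data$reward,
                                      colour = factor(.data$horizon))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = sel,
                        ggplot2::aes(x = .data$hit_value, y = .data$reward),
                        size = 2) +
    ggplot2::labs(x = "Hit value (points)", y = "Expected reward per trial",
                  colour = "Horizon") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
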