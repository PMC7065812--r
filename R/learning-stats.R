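#' Exponential learning-curve fit
#'
#' Fits `error = a * exp(b * trial) + c` by Levenberg-Marquardt nonlinear
#' least squares with multi-start initialization: `a0` = first minus last
#' observed error, `c0` = last observed error, and `b0` drawn from a small
#' set of plausible decay rates. The best converged start (lowest residual
#' sum of squares) is kept.
#'
#' @param errors Per-trial errors (mm or degrees).
#' @param trials Trial indices (defaults to `1:n`).
#' @param b_starts Initial decay rates tried.
#' @return A list of class `ll_expfit`: `a`, `b`, `c`, `r2`, `sse`,
#'   `converged`, `b_identifiable` (`FALSE` when the data are flat so the
#'   rate is meaningless), `fitted`, `trials`.
#' @examples
#' y <- 100 * exp(-0.05 * (1:200)) + 30
#' fit_exponential(y)$b # -0.05
#' @export
fit_exponential <- function(errors, trials = seq_along(errors),
                            b_starts = c(-0.1, -0.03, -0.01)) {
  if (length(errors) < 4) abort("need at least 4 trials to fit.")
  if (length(trials) != length(errors)) abort("length mismatch.")
  y <- as.numeric(errors)
  x <- as.numeric(trials)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    # flat data: amplitude 0, asymptote at the constant level, rate moot
    return(structure(
      list(a = 0, b = 0, c = y[1], r2 = NA_real_, sse = 0,
           converged = TRUE, b_identifiable = FALSE,
           fitted = y, trials = x),
      class = "ll_expfit"
    ))
  }
  a0 <- y[1] - y[length(y)]
  c0 <- y[length(y)]
  best <- NULL
  for (b0 in b_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * exp(b * x) + c,
        start = list(a = a0, b = b0, c = c0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    return(structure(
      list(a = NA_real_, b = NA_real_, c = NA_real_, r2 = NA_real_,
           sse = NA_real_, converged = FALSE, b_identifiable = FALSE,
           fitted = rep(NA_real_, length(y)), trials = x),
      class = "ll_expfit"
    ))
  }
  cf <- coef(best$fit)
  structure(
    list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
         r2 = 1 - best$sse / sst, sse = best$sse,
         converged = TRUE,
         b_identifiable = abs(unname(cf["a"])) > sqrt(.Machine$double.eps),
         fitted = as.numeric(stats::fitted(best$fit)), trials = x),
    class = "ll_expfit"
  )
}

#' @export
print.ll_expfit <- function(x, ...) {
  if (!x$converged) {
    cat("<ll_expfit> did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("<ll_expfit> %.3g * exp(%.4g * trial) + %.3g  (R^2 = %.3f)\n",
              x$a, x$b, x$c, x$r2))
  invisible(x)
}

#' @method tidy ll_expfit
#' @export
tidy.ll_expfit <- function(x, ...) {
  tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c))
}

#' @method glance ll_expfit
#' @export
glance.ll_expfit <- function(x, ...) {
  tibble(a = x$a, b = x$b, c = x$c, r2 = x$r2, sse = x$sse,
         converged = x$converged, b_identifiable = x$b_identifiable)
}

#' @method augment ll_expfit
#' @export
augment.ll_expfit <- function(x, ...) {
  tibble(trial = x$trials, fitted = x$fitted)
}

#' First- versus last-block movement error
#'
#' Per-participant mean error over the first and last block of trials,
#' compared by a paired t test (df = participants - 1).
#'
#' @param sessions List (or tibble) of sessions carrying `errors`.
#' @param cfg [experiment_config()].
#' @return A one-row tibble: `mean_first`, `se_first`, `mean_last`,
#'   `se_last`, `t`, `df`, `p_value`, `n`.
#' @export
block_comparison <- function(sessions, cfg = experiment_config()) {
  sessions <- as_session_list(sessions)
  if (length(sessions) < 2) abort("need at least 2 participants.")
  bs <- cfg$block_size
  first <- purrr::map_dbl(sessions, ~ mean(.x$errors[seq_len(bs)]))
  last <- purrr::map_dbl(sessions, ~ mean(tail(.x$errors, bs)))
  n <- length(sessions)
  d <- first - last
  if (sd(d) == 0) {
    # degenerate paired differences: identical blocks give t = 0
    tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    df <- n - 1
    p <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- stats::t.test(first, last, paired = TRUE)
    tstat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  tibble(
    mean_first = mean(first), se_first = sd(first) / sqrt(n),
    mean_last = mean(last), se_last = sd(last) / sqrt(n),
    t = tstat, df = df, p_value = p, n = n
  )
}

#' Performance aligned on target switches
#'
#' Collapses, across all decisions at which the selected target actually
#' changed, the trials before and after the switch, and averages hit rate,
#' selected target index, and per-trial reward — first within, then across
#' participants. Windows that would run past the session edges are dropped.
#'
#' @param sessions List (or tibble) of sessions carrying `errors` and
#'   `choices`.
#' @param targets [target_set()]; its `hit_margin` sets the hit convention.
#' @param cfg [experiment_config()].
#' @param window Trials kept on each side of the switch.
#' @return A tibble: `position` (-window..-1 before, 1..window after the
#'   switch), `hit_rate`, `target_index`, `reward`, `n_participants`.
#'   Zero rows (with a warning) if no participant ever switched.
#' @export
switch_aligned_average <- function(sessions, targets,
                                   cfg = experiment_config(), window = 5L) {
  sessions <- as_session_list(sessions)
  bs <- cfg$block_size
  per_part <- purrr::map(sessions, function(s) {
    block_targets <- c(1L, as.integer(s$choices))
    trial_target <- rep(block_targets, each = bs)
    hit <- hit_matrix(s$errors, targets)[cbind(seq_along(s$errors), trial_target)]
    reward <- targets$values[trial_target] * hit
    switch_j <- which(diff(block_targets) != 0L)
    if (!length(switch_j)) return(NULL)
    rows <- purrr::map(switch_j, function(j) {
      t0 <- bs * j # last trial before the switch takes effect
      pre <- (t0 - window + 1L):t0
      post <- (t0 + 1L):(t0 + window)
      idx <- c(pre, post)
      if (min(idx) < 1L || max(idx) > cfg$n_trials) return(NULL)
      tibble(position = c(-(window:1), 1:window),
             hit = hit[idx], target_index = trial_target[idx],
             reward = reward[idx])
    })
    rows <- purrr::compact(rows)
    if (!length(rows)) return(NULL)
    dplyr::bind_rows(rows) |>
      dplyr::group_by(.data$position) |>
      dplyr::summarise(hit_rate = mean(.data$hit),
                       target_index = mean(.data$target_index),
                       reward = mean(.data$reward), .groups = "drop")
  })
  per_part <- purrr::compact(per_part)
  if (!length(per_part)) {
    warn("no target switches in any session.")
    return(tibble(position = integer(), hit_rate = numeric(),
                  target_index = numeric(), reward = numeric(),
                  n_participants = integer()))
  }
  dplyr::bind_rows(per_part) |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(hit_rate = mean(.data$hit_rate),
                     target_index = mean(.data$target_index),
                     reward = mean(.data$reward),
                     n_participants = dplyr::n(), .groups = "drop")
}

# rows of `embed` run backwards in time; irrelevant for the moments used here
roll_windows <- function(v, window) {
  stats::embed(v, window)
}

#' Moving-window bias-variance decomposition of endpoint error
#'
#' Over a moving window of trials (9 by default, full windows only), the
#' mean endpoint position estimates the bias and the standard deviation (n-1
#' denominator) the variability, separately for x and y. Since the
#' mean squared error decomposes as `MSE = bias^2 + variance`, the fraction
#' `bias^2 / (bias^2 + variance)` reports how much of the error is
#' systematic.
#'
#' @param final_x,final_y Endpoint coordinates relative to the target centre
#'   (mm), y positive up-screen (overshoot).
#' @param window Window width in trials (odd; the default 9).
#' @return A tibble: `center_trial`, `mean_x`, `mean_y`, `sd_x`, `sd_y`,
#'   `bias_fraction_x`, `bias_fraction_y`.
#' @export
moving_bias_variance <- function(final_x, final_y, window = 9L) {
  n <- length(final_x)
  if (length(final_y) != n) abort("x and y must have equal length.")
  if (n < window) abort("need at least `window` trials.")
  half <- (window - 1L) %/% 2L
  wx <- roll_windows(final_x, window)
  wy <- roll_windows(final_y, window)
  mx <- rowMeans(wx); my <- rowMeans(wy)
  sdx <- sqrt(rowSums((wx - mx)^2) / (window - 1))
  sdy <- sqrt(rowSums((wy - my)^2) / (window - 1))
  tibble(
    center_trial = (window:n) - half,
    mean_x = mx, mean_y = my, sd_x = sdx, sd_y = sdy,
    bias_fraction_x = mx^2 / (mx^2 + sdx^2),
    bias_fraction_y = my^2 / (my^2 + sdy^2)
  )
}

#' Moving-window correlation between x and y endpoint error
#'
#' Pearson correlation of the x and y endpoint coordinates over the same
#' moving window as [moving_bias_variance()]. Windows in which either
#' coordinate is constant yield `NA` (undefined correlation).
#'
#' @inheritParams moving_bias_variance
#' @return A tibble: `center_trial`, `r`.
#' @export
xy_error_correlation <- function(final_x, final_y, window = 9L) {
  n <- length(final_x)
  if (length(final_y) != n) abort("x and y must have equal length.")
  if (n < window) abort("need at least `window` trials.")
  half <- (window - 1L) %/% 2L
  wx <- roll_windows(final_x, window)
  wy <- roll_windows(final_y, window)
  mx <- rowMeans(wx); my <- rowMeans(wy)
  sxy <- rowSums((wx - mx) * (wy - my))
  sxx <- rowSums((wx - mx)^2)
  syy <- rowSums((wy - my)^2)
  r <- ifelse(sxx > 0 & syy > 0, sxy / sqrt(sxx * syy), NA_real_)
  if (anyNA(r)) warn("zero-variance window(s): correlation undefined there.")
  tibble(center_trial = (window:n) - half, r = r)
}
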