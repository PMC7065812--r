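#' Fit a windowed decision policy to observed choices
#'
#' Exhaustive grid search for the (lead, lag) window whose sequential
#' rollout best reproduces an observed choice sequence, minimizing the sum
#' of squared differences between predicted and observed target indices over
#' all decision points. For robustness only windows with `lead + lag >= 5`
#' are considered. The one-parameter variants fix the other window at zero:
#' `mode = "lead"` searches lag = 0, `mode = "lag"` searches lead = 0.
#' Ties are broken toward the smaller `lead + lag`, then the smaller lead.
#'
#' @inheritParams window_value
#' @param observed Observed target indices, one per decision point.
#' @param mode `"leadlag"`, `"lead"`, or `"lag"`.
#' @param lead_range,lag_range Window lengths searched (clamped internally
#'   by `min_window`).
#' @param min_window Minimum admissible `lead + lag`.
#' @return A list of class `ll_fit`: `policy`, `sse`, `mad` (mean absolute
#'   deviation in target-index units), `r2` (1 - SSE/SST about the observed
#'   mean; `NA` when the observed choices are constant), `predicted`,
#'   `observed`, `mode`, `n_obs`.
#' @examples
#' cfg <- experiment_config()
#' ts <- target_set()
#' err <- pmax(0, 250 * exp(-0.02 * (1:200)) + 10)
#' truth <- rollout_policy(err, policy_params(18, 14), ts, cfg)
#' fit <- fit_policy(truth$choices, err, ts, cfg,
#'                   lead_range = 0:30, lag_range = 0:30)
#' fit$sse # 0: the generating policy is in the grid
#' @export
fit_policy <- function(observed, errors, targets, cfg = experiment_config(),
                       mode = c("leadlag", "lead", "lag"),
                       lead_range = 0:(cfg$n_trials - cfg$block_size),
                       lag_range = 0:(cfg$n_trials - 1),
                       min_window = 5L) {
  mode <- match.arg(mode)
  check_errors(errors, cfg)
  observed <- as.integer(observed)
  if (length(observed) != cfg$n_decisions) {
    abort(paste0("`observed` must have length ", cfg$n_decisions, "."))
  }
  if (mode == "lead") lag_range <- 0L
  if (mode == "lag") lead_range <- 0L
  lead_range <- sort(unique(as.integer(lead_range)))
  lag_range <- sort(unique(as.integer(lag_range)))
  cs <- cum_hits(errors, targets)
  best <- NULL
  for (lead in lead_range) {
    for (lag in lag_range) {
      if (lead + lag < min_window) next
      pred <- rollout_choices(cs, targets, cfg, lead, lag)
      sse <- sum((pred - observed)^2)
      key <- c(sse, lead + lag, lead)
      if (is.null(best) || lexico_less(key, best$key)) {
        best <- list(key = key, lead = lead, lag = lag, pred = pred)
      }
    }
  }
  if (is.null(best)) abort("no admissible (lead, lag) in the search grid.")
  sst <- sum((observed - mean(observed))^2)
  structure(
    list(policy = policy_params(best$lead, best$lag),
         sse = best$key[1],
         mad = mean(abs(best$pred - observed)),
         r2 = if (sst > 0) 1 - best$key[1] / sst else NA_real_,
         predicted = best$pred,
         observed = observed,
         mode = mode,
         n_obs = length(observed)),
    class = "ll_fit"
  )
}

lexico_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' @export
print.ll_fit <- function(x, ...) {
  cat("<ll_fit> mode =", x$mode, "| lead =", x$policy$lead,
      "lag =", x$policy$lag, "\n")
  cat(sprintf("SSE = %.3g | MAD = %.3g | R^2 = %.3g\n", x$sse, x$mad, x$r2))
  invisible(x)
}

#' @method tidy ll_fit
#' @export
tidy.ll_fit <- function(x, ...) {
  tibble(term = c("lead", "lag"),
         estimate = c(x$policy$lead, x$policy$lag))
}

#' @method glance ll_fit
#' @export
glance.ll_fit <- function(x, ...) {
  tibble(mode = x$mode, lead = x$policy$lead, lag = x$policy$lag,
         sse = x$sse, mad = x$mad, r2 = x$r2, n_obs = x$n_obs)
}

#' @method augment ll_fit
#' @export
augment.ll_fit <- function(x, ...) {
  tibble(decision = seq_along(x$observed),
         observed = x$observed, predicted = x$predicted,
         residual = x$observed - x$predicted)
}

#' Fit a policy to every participant and pool the residuals
#'
#' Fits the requested model independently to each participant (separate
#' lead and/or lag parameters per participant, 1 or 2 each) and pools the
#' squared residuals, so the pooled model has `participants x params` free
#' parameters over `participants x n_decisions` observations.
#'
#' @param sessions A list of sessions; each must carry `choices` (observed
#'   target indices) and `errors` (per-trial mm). A tibble of sessions from
#'   [simulate_throw_cohort()] works directly.
#' @inheritParams fit_policy
#' @param ... Passed on to [fit_policy()] (e.g. `lead_range`).
#' @return A list of class `ll_pooled`: `fits` (per-participant `ll_fit`s),
#'   `sse` (pooled), `mad` (pooled mean absolute deviation), `n_obs`,
#'   `n_params`, `mode`.
#' @export
pooled_fit <- function(sessions, targets, cfg = experiment_config(),
                       mode = c("leadlag", "lead", "lag"), ...) {
  mode <- match.arg(mode)
  sessions <- as_session_list(sessions)
  if (!length(sessions)) abort("`sessions` must be non-empty.")
  fits <- purrr::map(sessions, function(s) {
    fit_policy(s$choices, s$errors, targets, cfg, mode = mode, ...)
  })
  per_param <- if (mode == "leadlag") 2L else 1L
  structure(
    list(fits = fits,
         sse = sum(purrr::map_dbl(fits, "sse")),
         mad = mean(purrr::map_dbl(fits, "mad")),
         n_obs = sum(purrr::map_int(fits, "n_obs")),
         n_params = per_param * length(fits),
         mode = mode),
    class = "ll_pooled"
  )
}

#' @export
print.ll_pooled <- function(x, ...) {
  cat("<ll_pooled> mode =", x$mode, "|", length(x$fits), "participants |",
      x$n_params, "parameters\n")
  cat(sprintf("pooled SSE = %.4g | mean MAD = %.3g\n", x$sse, x$mad))
  invisible(x)
}

#' @method tidy ll_pooled
#' @export
tidy.ll_pooled <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, i) {
    dplyr::mutate(glance(f), participant = i, .before = 1)
  })
}

#' @method glance ll_pooled
#' @export
glance.ll_pooled <- function(x, ...) {
  tibble(mode = x$mode, sse = x$sse, mad = x$mad,
         n_obs = x$n_obs, n_params = x$n_params)
}

#' Nested-model F test on pooled residuals
#'
#' Compares a reduced against a full model fitted to the same observations:
#' `F = ((SSE_r - SSE_f) / (p_f - p_r)) / (SSE_f / (n - p_f))`, with
#' `(p_f - p_r, n - p_f)` degrees of freedom. With one numerator degree of
#' freedom this is the square of the usual t statistic.
#'
#' @param reduced,full Either `ll_pooled`/`ll_fit` objects or raw SSE
#'   numbers (in which case `params_reduced`, `params_full`, `n_obs` must be
#'   given).
#' @param params_reduced,params_full,n_obs Overrides when passing raw SSEs.
#' @return A one-row tibble of class `ll_ftest`: `f_stat`, `df_num`,
#'   `df_den`, `p_value`, plus the inputs.
#' @examples
#' nested_f_test(524, 347, params_reduced = 8, params_full = 16, n_obs = 312)
#' @export
nested_f_test <- function(reduced, full,
                          params_reduced = NULL, params_full = NULL,
                          n_obs = NULL) {
  pull_sse <- function(x, p, n) {
    if (inherits(x, c("ll_pooled", "ll_fit"))) {
      list(sse = x$sse,
           p = x$n_params %||% (if (x$mode == "leadlag") 2L else 1L),
           n = x$n_obs)
    } else {
      list(sse = as.numeric(x), p = p, n = n)
    }
  }
  r <- pull_sse(reduced, params_reduced, n_obs)
  f <- pull_sse(full, params_full, n_obs)
  if (is.null(r$p) || is.null(f$p) || is.null(f$n)) {
    abort("parameter counts and `n_obs` are required with raw SSE inputs.")
  }
  if (f$p <= r$p) abort("the full model must have more parameters.")
  if (f$n <= f$p) abort("`n_obs` must exceed the full model's parameters.")
  df1 <- f$p - r$p
  df2 <- f$n - f$p
  fstat <- ((r$sse - f$sse) / df1) / (f$sse / df2)
  out <- tibble(
    f_stat = fstat, df_num = df1, df_den = df2,
    p_value = pf(fstat, df1, df2, lower.tail = FALSE),
    sse_reduced = r$sse, sse_full = f$sse
  )
  class(out) <- c("ll_ftest", class(out))
  out
}

#' @method tidy ll_ftest
#' @export
tidy.ll_ftest <- function(x, ...) {
  tibble(statistic = x$f_stat, df_num = x$df_num, df_den = x$df_den,
         p.value = x$p_value)
}

#' Sensitivity of the fit to offsets around the best window
#'
#' Recomputes the variance explained (R^2 of predicted vs observed choices)
#' as the lead and lag are displaced from each participant's best-fitting
#' values, then averages across participants. With `fold = TRUE` the
#' surface is indexed by offset magnitude, averaging the positive and
#' negative displacement of each size; offsets that would push a window
#' negative are dropped for that participant.
#'
#' @param fits List of `ll_fit` objects (or an `ll_pooled`).
#' @param sessions Sessions matching `fits` (for `choices`/`errors`).
#' @inheritParams fit_policy
#' @param offsets Offset magnitudes, e.g. `0:10`.
#' @param fold Average +/- offsets of equal magnitude (the default) or
#'   return the signed surface.
#' @return A tibble: `lead_offset`, `lag_offset`, `r2` (mean across
#'   participants), `n_participants` contributing to the cell.
#' @export
sensitivity_surface <- function(fits, sessions, targets,
                                cfg = experiment_config(),
                                offsets = 0:10, fold = TRUE) {
  if (inherits(fits, "ll_pooled")) fits <- fits$fits
  sessions <- as_session_list(sessions)
  if (length(fits) != length(sessions)) {
    abort("`fits` and `sessions` must have the same length.")
  }
  signed <- if (fold) offsets else sort(unique(c(-offsets, offsets)))
  per_part <- purrr::map2(fits, sessions, function(fit, s) {
    obs <- as.integer(s$choices)
    sst <- sum((obs - mean(obs))^2)
    if (sst == 0) {
      warn("constant observed choices: R^2 undefined for one participant.")
      return(NULL)
    }
    cs <- cum_hits(s$errors, targets)
    r2_at <- function(lead, lag) {
      if (lead < 0 || lag < 0) return(NA_real_)
      pred <- rollout_choices(cs, targets, cfg, lead, lag)
      1 - sum((pred - obs)^2) / sst
    }
    grid <- tidyr::expand_grid(lead_offset = signed, lag_offset = signed)
    grid$r2 <- purrr::map2_dbl(grid$lead_offset, grid$lag_offset, function(dl, dg) {
      if (fold) {
        # average the +/- displacements of this magnitude that exist
        combos <- tidyr::expand_grid(sl = unique(c(dl, -dl)),
                                     sg = unique(c(dg, -dg)))
        vals <- purrr::map2_dbl(combos$sl, combos$sg, function(a, b) {
          r2_at(fit$policy$lead + a, fit$policy$lag + b)
        })
        if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
      } else {
        r2_at(fit$policy$lead + dl, fit$policy$lag + dg)
      }
    })
    grid
  })
  per_part <- purrr::compact(per_part)
  if (!length(per_part)) abort("no participant with non-constant choices.")
  dplyr::bind_rows(per_part) |>
    dplyr::group_by(.data$lead_offset, .data$lag_offset) |>
    dplyr::summarise(n_participants = sum(!is.na(.data$r2)),
                     r2 = mean(.data$r2, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::relocate("r2", .after = "lag_offset")
}

# accepts a plain list of sessions, or a tibble with list-columns
# `choices` and `errors` (one row per participant)
as_session_list <- function(sessions) {
  if (is.data.frame(sessions)) {
    purrr::pmap(list(sessions$choices, sessions$errors),
                function(ch, er) list(choices = ch, errors = er))
  } else {
    sessions
  }
}
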