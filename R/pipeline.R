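#' End-to-end throwing-task analysis
#'
#' Runs the full Experiment-1 style pipeline over a cohort: per-participant
#' global optimum (with exact scenario rank/percentile/z-score of the
#' actual choices), best local lead-lag policy for realized reward, the
#' three choice-fitting models (lead, lag, lead-lag) with pooled and
#' per-participant nested F tests, and the learning statistics
#' (first-vs-last block comparison, exponential fits, switch-aligned
#' averages).
#'
#' @param sessions Cohort tibble from [simulate_throw_cohort()] or list of
#'   throw sessions with `errors` and `choices`.
#' @param targets [target_set()] used for model valuation and scoring.
#' @param cfg [experiment_config()].
#' @param lead_range,lag_range Grid searched for local-optimal and fitted
#'   policies.
#' @param sensitivity_offsets Offset magnitudes for the sensitivity
#'   surface (`NULL` to skip).
#' @param seed Seed recorded in the provenance block (the pipeline itself
#'   is deterministic).
#' @return A list of class `ll_exp1_report`: `participants` (tibble),
#'   `model_comparison` (pooled fits + F tests), `per_participant_tests`,
#'   `learning` (block comparison + exponential fit summaries),
#'   `switch_aligned`, `sensitivity`, `provenance`.
#' @export
run_exp1 <- function(sessions, targets = target_set(),
                     cfg = experiment_config(),
                     lead_range = 0:120, lag_range = 0:120,
                     sensitivity_offsets = 0:10, seed = NA_integer_) {
  slist <- as_session_list(sessions)
  n <- length(slist)
  if (!n) abort("no sessions supplied.")

  per <- purrr::imap(slist, function(s, i) {
    actual_points <- score_points(s$errors, s$choices, targets, cfg)
    dp <- global_optimal_dp(s$errors, targets, cfg)
    dist <- scenario_distribution(s$errors, targets, cfg)
    rank <- scenario_rank(dist, actual_points)
    loc <- local_optimal_search(s$errors, targets, cfg,
                                lead_range = lead_range,
                                lag_range = lag_range)
    fits <- purrr::map(
      c(leadlag = "leadlag", lead = "lead", lag = "lag"),
      ~ fit_policy(s$choices, s$errors, targets, cfg, mode = .x,
                   lead_range = lead_range, lag_range = lag_range)
    )
    expfit <- fit_exponential(s$errors)
    list(
      row = tibble(
        participant = i,
        actual_points = actual_points,
        optimal_points = dp$points,
        optimal_percentile = rank$percentile,
        optimal_zscore = rank$zscore,
        local_optimal_points = loc$points,
        local_lead = loc$policy$lead, local_lag = loc$policy$lag,
        fitted_lead = fits$leadlag$policy$lead,
        fitted_lag = fits$leadlag$policy$lag,
        fitted_points = score_points(s$errors, fits$leadlag$predicted,
                                     targets, cfg),
        sse_leadlag = fits$leadlag$sse, sse_lead = fits$lead$sse,
        sse_lag = fits$lag$sse,
        mad_leadlag = fits$leadlag$mad, mad_lead = fits$lead$mad,
        mad_lag = fits$lag$mad,
        curve_a = expfit$a, curve_b = expfit$b, curve_c = expfit$c,
        curve_r2 = expfit$r2
      ),
      fits = fits
    )
  })
  participants <- dplyr::bind_rows(purrr::map(per, "row"))

  pool <- function(mode) {
    fits <- purrr::map(per, ~ .x$fits[[mode]])
    structure(
      list(fits = fits, sse = sum(purrr::map_dbl(fits, "sse")),
           mad = mean(purrr::map_dbl(fits, "mad")),
           n_obs = sum(purrr::map_int(fits, "n_obs")),
           n_params = (if (mode == "leadlag") 2L else 1L) * n,
           mode = mode),
      class = "ll_pooled"
    )
  }
  pooled <- purrr::map(c(leadlag = "leadlag", lead = "lead", lag = "lag"),
                       pool)
  f_tests <- NULL
  if (n >= 1 && pooled$leadlag$n_obs > pooled$leadlag$n_params) {
    f_tests <- dplyr::bind_rows(
      dplyr::mutate(nested_f_test(pooled$lead, pooled$leadlag),
                    comparison = "leadlag vs lead", .before = 1),
      dplyr::mutate(nested_f_test(pooled$lag, pooled$leadlag),
                    comparison = "leadlag vs lag", .before = 1)
    )
  }
  per_tests <- purrr::imap_dfr(per, function(p, i) {
    dplyr::bind_rows(
      dplyr::mutate(nested_f_test(p$fits$lead, p$fits$leadlag),
                    participant = i, comparison = "leadlag vs lead",
                    .before = 1),
      dplyr::mutate(nested_f_test(p$fits$lag, p$fits$leadlag),
                    participant = i, comparison = "leadlag vs lag",
                    .before = 1)
    )
  })

  learning <- if (n >= 2) block_comparison(slist, cfg)
  sw <- switch_aligned_average(slist, targets, cfg)
  sens <- if (!is.null(sensitivity_offsets)) {
    sensitivity_surface(purrr::map(per, ~ .x$fits$leadlag), slist, targets,
                        cfg, offsets = sensitivity_offsets)
  }

  structure(
    list(participants = participants,
         model_comparison = list(pooled = purrr::map_dfr(pooled, glance),
                                 f_tests = f_tests),
         per_participant_tests = per_tests,
         learning = learning,
         switch_aligned = sw,
         sensitivity = sens,
         provenance = report_provenance(seed, list(
           targets = unclass(targets), cfg = unclass(cfg),
           lead_range = range(lead_range), lag_range = range(lag_range)
         ))),
    class = "ll_exp1_report"
  )
}

#' @export
print.ll_exp1_report <- function(x, ...) {
  n <- nrow(x$participants)
  cat("<ll_exp1_report>", n, "participants\n")
  cat(sprintf("mean points: actual %.1f | global optimal %.1f | local optimal %.1f\n",
              mean(x$participants$actual_points),
              mean(x$participants$optimal_points),
              mean(x$participants$local_optimal_points)))
  cat(sprintf("pooled SSE: leadlag %.0f | lead %.0f | lag %.0f\n",
              x$model_comparison$pooled$sse[1],
              x$model_comparison$pooled$sse[2],
              x$model_comparison$pooled$sse[3]))
  invisible(x)
}

#' End-to-end reward-schedule (horizon) analysis
#'
#' Runs the Experiment-2 style pipeline over a cohort of reach sessions:
#' per-participant hit proportions and expected-reward lines per horizon,
#' optimal/minimum/maximum/actual rewards, repeated-measures ANOVAs of hit
#' proportion and selected hit value across horizons with Holm-corrected
#' paired t tests, the horizon-adjusted correlation between reward slope
#' and selected hit value, and its cross-validated predictive counterpart.
#'
#' @param sessions List of `ll_reach_session` objects.
#' @param cfg [exp2_config()].
#' @param include_faults Keep faults in hit-proportion denominators.
#' @param cv_reps,cv_perms Monte-Carlo repetitions and permutations for
#'   [cv_predictive_r()].
#' @param seed Seed for the cross-validation resampling (and recorded in
#'   provenance).
#' @return A list of class `ll_exp2_report`: `points` (participant x
#'   horizon tibble), `hit_anova`, `hit_value_anova`, `pairwise` (Holm),
#'   `adjusted_cor`, `cv_cor`, `rewards`, `provenance`.
#' @export
run_exp2 <- function(sessions, cfg = exp2_config(), include_faults = TRUE,
                     cv_reps = 1000L, cv_perms = 999L, seed = 1L) {
  if (!length(sessions)) abort("no sessions supplied.")
  points_tbl <- purrr::imap_dfr(sessions, function(s, i) {
    harvest <- s$trials$outcome[s$trials$phase == "harvest"]
    if (!length(harvest)) abort("session without harvest trials.")
    purrr::map_dfr(cfg$horizons, function(H) {
      line <- reward_line(harvest, horizon = H, cfg = cfg,
                          include_faults = include_faults)
      sel <- s$selected_hit_values[[as.character(H)]]
      ext <- reward_extremes(line, sel, cfg)
      dplyr::bind_cols(
        tibble(participant = i, horizon = H,
               hit_value = as.numeric(sel)),
        dplyr::select(line, -"horizon"),
        ext[, c("min_reward", "max_reward", "actual_reward", "optimal_v")]
      )
    })
  })

  hit_anova <- rm_anova(dplyr::transmute(points_tbl,
                                         participant = .data$participant,
                                         condition = .data$horizon,
                                         value = .data$hit_prop))
  value_anova <- rm_anova(dplyr::transmute(points_tbl,
                                           participant = .data$participant,
                                           condition = .data$horizon,
                                           value = .data$hit_value))

  pairs <- utils::combn(cfg$horizons, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    a <- dplyr::filter(points_tbl, .data$horizon == pr[1])
    b <- dplyr::filter(points_tbl, .data$horizon == pr[2])
    tt_hit <- stats::t.test(a$hit_prop, b$hit_prop, paired = TRUE)
    tt_val <- stats::t.test(a$hit_value, b$hit_value, paired = TRUE)
    tibble(comparison = paste(pr[1], pr[2], sep = "-"),
           measure = c("hit_prop", "hit_value"),
           t = c(unname(tt_hit$statistic), unname(tt_val$statistic)),
           df = c(unname(tt_hit$parameter), unname(tt_val$parameter)),
           p = c(tt_hit$p.value, tt_val$p.value))
  })
  pairwise <- pairwise |>
    dplyr::group_by(.data$measure) |>
    dplyr::mutate(holm_bonferroni(.data$p)[, c("p_adjusted", "reject")]) |>
    dplyr::ungroup()

  adj <- adjusted_correlation(points_tbl)
  cv <- cv_predictive_r(points_tbl, reps = cv_reps, perms = cv_perms,
                        seed = seed)

  rewards <- points_tbl |>
    dplyr::group_by(.data$horizon) |>
    dplyr::summarise(hit_prop = mean(.data$hit_prop),
                     hit_value = mean(.data$hit_value),
                     actual_reward = mean(.data$actual_reward),
                     max_reward = mean(.data$max_reward),
                     min_reward = mean(.data$min_reward),
                     .groups = "drop")

  structure(
    list(points = points_tbl,
         hit_anova = hit_anova, hit_value_anova = value_anova,
         pairwise = pairwise, adjusted_cor = adj, cv_cor = cv,
         rewards = rewards,
         provenance = report_provenance(seed, list(
           cfg = unclass(cfg), include_faults = include_faults,
           cv_reps = cv_reps, cv_perms = cv_perms
         ))),
    class = "ll_exp2_report"
  )
}

#' @export
print.ll_exp2_report <- function(x, ...) {
  cat("<ll_exp2_report>", length(unique(x$points$participant)),
      "participants\n")
  print(x$rewards)
  cat(sprintf("adjusted r = %.3f (p = %.4f); CV predictive r = %.3f (p = %.4f)\n",
              x$adjusted_cor$r, x$adjusted_cor$p_value,
              x$cv_cor$r, x$cv_cor$p_value))
  invisible(x)
}

report_provenance <- function(seed, config) {
  # no timestamp: reports must be byte-identical under a fixed seed
  tibble(
    package_version = as.character(utils::packageVersion("leadlag")),
    seed = as.integer(seed),
    config_hash = rlang::hash(config)
  )
}

#' Serialize a report to JSON
#'
#' @param report An `ll_exp1_report` or `ll_exp2_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  stripped <- purrr::map(unclass(report), function(x) {
    if (inherits(x, "ll_pooled")) glance(x) else x
  })
  jsonlite::write_json(stripped, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
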