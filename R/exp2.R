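#' Angular hit threshold of the reaching task
#'
#' The directional tolerance for a hit: a target of radius `target_radius`
#' at reach amplitude `amplitude` subtends `radius / amplitude` radians, so
#' the default geometry (10 mm at 100 mm) gives 0.1 rad = 5.73 degrees.
#'
#' @param cfg [exp2_config()].
#' @return Threshold in degrees.
#' @examples
#' angular_threshold() # 5.7296
#' @export
angular_threshold <- function(cfg = exp2_config()) {
  if (cfg$amplitude <= 0) abort("`amplitude` must be positive.")
  (cfg$target_radius / cfg$amplitude) * 180 / pi
}

#' Classify reach trials as hit, miss, or fault
#'
#' A trial is a fault when the reaction time exceeds the fault criterion
#' (350 ms); otherwise it is a hit when the absolute angular error is within
#' the [angular_threshold()] (boundary inclusive), else a miss.
#'
#' @param angular_error Angular errors in degrees (vectorized).
#' @param reaction_time Reaction times in ms.
#' @param cfg [exp2_config()].
#' @return Character vector: `"hit"`, `"miss"`, or `"fault"`.
#' @examples
#' classify_trials(c(0, 5.73, 10, 0), c(200, 200, 200, 360))
#' @export
classify_trials <- function(angular_error, reaction_time, cfg = exp2_config()) {
  if (length(angular_error) != length(reaction_time)) abort("length mismatch.")
  thr <- angular_threshold(cfg)
  out <- ifelse(reaction_time > cfg$rt_fault, "fault",
                ifelse(abs(angular_error) <= thr, "hit", "miss"))
  out
}

#' Expected-reward line for a horizon
#'
#' Over the first `horizon` harvest trials, the hit/miss/fault proportions
#' (h, m, f; summing to 1) determine the expected per-trial reward as a
#' function of the chosen hit value `v`:
#' `E(v) = h * v + m * (schedule_sum - v)` (faults score 0), a line with
#' slope `h - m` and intercept `schedule_sum * m`.
#'
#' @param outcomes Character vector of classified outcomes
#'   (`"hit"`/`"miss"`/`"fault"`) for the harvest trials of one horizon, in
#'   trial order; the first `horizon` entries are used (all, if `horizon`
#'   is `NULL`).
#' @param horizon Number of harvest trials to include.
#' @param cfg [exp2_config()].
#' @param include_faults Count faults in the denominator (the default) or
#'   drop them before computing proportions.
#' @return A one-row tibble of class `ll_reward_line`: `horizon`,
#'   `hit_prop`, `miss_prop`, `fault_prop`, `slope`, `intercept`.
#' @examples
#' reward_line(rep(c("hit", "miss"), 5))$slope # 0
#' @export
reward_line <- function(outcomes, horizon = NULL, cfg = exp2_config(),
                        include_faults = TRUE) {
  if (!length(outcomes)) abort("`outcomes` must be non-empty.")
  if (!is.null(horizon)) {
    if (horizon > length(outcomes)) {
      abort("`horizon` exceeds the available harvest trials.")
    }
    outcomes <- outcomes[seq_len(horizon)]
  }
  bad <- setdiff(unique(outcomes), c("hit", "miss", "fault"))
  if (length(bad)) abort(paste("unknown outcome:", bad[1]))
  if (!include_faults) outcomes <- outcomes[outcomes != "fault"]
  if (!length(outcomes)) abort("no trials left after excluding faults.")
  n <- length(outcomes)
  h <- sum(outcomes == "hit") / n
  m <- sum(outcomes == "miss") / n
  f <- sum(outcomes == "fault") / n
  out <- tibble(
    horizon = horizon %||% n,
    hit_prop = h, miss_prop = m, fault_prop = f,
    slope = h - m, intercept = cfg$schedule_sum * m
  )
  class(out) <- c("ll_reward_line", class(out))
  out
}

#' Expected per-trial reward at a hit value
#'
#' @param line A [reward_line()].
#' @param v Hit value(s).
#' @return Expected per-trial reward `slope * v + intercept`.
#' @export
expected_reward <- function(line, v) {
  line$slope * v + line$intercept
}

#' Optimal hit value for a reward line
#'
#' The expected reward is linear in the hit value, so the optimum sits at an
#' end of the admissible range: the highest hit value when the slope is
#' positive (good performance), the lowest when negative, and any value
#' when the slope is exactly zero (returned as `NA`, the indifferent case).
#'
#' @param line A [reward_line()].
#' @param cfg [exp2_config()].
#' @return The optimal hit value, or `NA` when indifferent.
#' @export
optimal_hit_value <- function(line, cfg = exp2_config()) {
  rng <- cfg$hit_value_range
  dplyr::case_when(
    line$slope > 0 ~ as.numeric(rng[2]),
    line$slope < 0 ~ as.numeric(rng[1]),
    .default = NA_real_
  )
}

#' Best, worst, and realized reward for a horizon
#'
#' Evaluates the expected per-trial reward at both ends of the hit-value
#' range and at the participant's actual selection; by linearity these
#' endpoints bound the reward for any admissible hit value.
#'
#' @param line A [reward_line()].
#' @param selected_v The hit value the participant selected.
#' @param cfg [exp2_config()].
#' @return A one-row tibble: `min_reward`, `max_reward`, `actual_reward`,
#'   `selected_v`, `optimal_v`.
#' @export
reward_extremes <- function(line, selected_v, cfg = exp2_config()) {
  rng <- cfg$hit_value_range
  if (selected_v < rng[1] || selected_v > rng[2]) {
    abort("`selected_v` outside the admissible hit-value range.")
  }
  ends <- expected_reward(line, as.numeric(rng))
  tibble(
    min_reward = min(ends), max_reward = max(ends),
    actual_reward = expected_reward(line, selected_v),
    selected_v = selected_v, optimal_v = optimal_hit_value(line, cfg)
  )
}

#' Horizon-adjusted correlation of hit value with reward slope
#'
#' Pools (slope, hit value) points across horizons after removing the mean
#' of each horizon from both variables and restoring the grand mean, then
#' reports the Pearson correlation of the adjusted values. This isolates
#' the within-horizon, across-participant association from the systematic
#' effect of horizon length.
#'
#' @param points A data frame with columns `horizon`, `slope`, `hit_value`
#'   (one row per participant x horizon).
#' @return A one-row tibble: `r`, `p_value`, `n`, plus the adjusted points
#'   in the list-column `adjusted`.
#' @export
adjusted_correlation <- function(points) {
  need <- c("horizon", "slope", "hit_value")
  if (!all(need %in% names(points))) {
    abort("`points` needs columns horizon, slope, hit_value.")
  }
  if (nrow(points) < 3) abort("need at least 3 points.")
  adj <- points |>
    dplyr::group_by(.data$horizon) |>
    dplyr::mutate(
      slope_adj = .data$slope - mean(.data$slope),
      hit_value_adj = .data$hit_value - mean(.data$hit_value)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      slope_adj = .data$slope_adj + mean(.data$slope),
      hit_value_adj = .data$hit_value_adj + mean(.data$hit_value)
    )
  if (sd(adj$slope_adj) == 0 || sd(adj$hit_value_adj) == 0) {
    warn("zero variance after adjustment: correlation undefined.")
    return(tibble(r = NA_real_, p_value = NA_real_, n = nrow(adj),
                  adjusted = list(adj)))
  }
  ct <- stats::cor.test(adj$slope_adj, adj$hit_value_adj)
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(adj),
         adjusted = list(adj))
}

# Out-of-fold SSEs for the linear and mean-only model, for every column of
# the response matrix Y at once, via per-fold sufficient statistics.
# x: predictor (n), Y: n x P responses, fold_id: n fold labels in 1..K.
cv_fold_sse <- function(x, Y, fold_id) {
  K <- max(fold_id)
  nk <- tabulate(fold_id, K)
  fx <- rowsum(x, fold_id)[, 1]
  fx2 <- rowsum(x^2, fold_id)[, 1]
  fy <- rowsum(Y, fold_id)
  fy2 <- rowsum(Y^2, fold_id)
  fxy <- rowsum(x * Y, fold_id)
  n <- length(x)
  ntr <- n - nk
  Sx <- sum(x) - fx
  Sx2 <- sum(x^2) - fx2
  Sy <- matrix(colSums(Y), K, ncol(Y), byrow = TRUE) - fy
  Sy2 <- matrix(colSums(Y^2), K, ncol(Y), byrow = TRUE) - fy2
  Sxy <- matrix(colSums(x * Y), K, ncol(Y), byrow = TRUE) - fxy
  den <- Sx2 - Sx^2 / ntr
  if (any(den <= 0)) return(NULL) # degenerate training fold
  b <- (Sxy - Sx * Sy / ntr) / den
  a <- (Sy - b * Sx) / ntr
  sse_lin <- unname(colSums(fy2 - 2 * a * fy - 2 * b * fxy +
                              a^2 * nk + 2 * a * b * fx + b^2 * fx2))
  mu <- Sy / ntr
  sse_mean <- unname(colSums(fy2 - 2 * mu * fy + mu^2 * nk))
  list(lin = sse_lin, mean = sse_mean)
}

#' Cross-validated predictive correlation
#'
#' Robustness check on a simple linear association: repeated random k-fold
#' cross-validation computes the out-of-fold predictive SSE of the linear
#' model and of a mean-only model; the predictive correlation is
#' `sign(slope) * sqrt(max(0, 1 - SSE_lin / SSE_mean))` with SSEs summed
#' over folds and Monte-Carlo repetitions. The p-value is obtained by
#' permuting the response across points and recomputing the statistic
#' (two-sided on the signed statistic).
#'
#' @param points Data frame with columns `slope` (predictor) and
#'   `hit_value` (response), or any data frame plus `x`/`y` column names.
#' @param folds Number of cross-validation folds.
#' @param reps Monte-Carlo repetitions (independent random fold splits).
#' @param perms Permutations for the p-value (0 to skip).
#' @param seed Integer seed.
#' @param x,y Column names of predictor and response.
#' @return A one-row tibble: `r` (predictive correlation), `p_value`, `n`,
#'   `folds`, `reps`.
#' @export
cv_predictive_r <- function(points, folds = 10L, reps = 1000L, perms = 1000L,
                            seed = 1L, x = "slope", y = "hit_value") {
  xv <- points[[x]]
  yv <- points[[y]]
  n <- length(xv)
  if (n < folds) abort("need at least `folds` points.")
  if (sd(xv) == 0) abort("constant predictor: slope undefined.")
  withr_seed(seed, {
    Y <- cbind(yv, if (perms > 0) {
      vapply(seq_len(perms), function(i) sample(yv), numeric(n))
    })
    sse_lin <- numeric(ncol(Y))
    sse_mean <- numeric(ncol(Y))
    r_done <- 0L
    while (r_done < reps) {
      fold_id <- sample(rep(seq_len(folds), length.out = n))
      res <- cv_fold_sse(xv, Y, fold_id)
      if (is.null(res)) next # resample degenerate splits
      sse_lin <- sse_lin + res$lin
      sse_mean <- sse_mean + res$mean
      r_done <- r_done + 1L
    }
    slope_sign <- sign(stats::cov(xv, Y[, 1]))
    stat <- function(k) {
      s <- sign(stats::cov(xv, Y[, k]))
      s * sqrt(max(0, 1 - sse_lin[k] / sse_mean[k]))
    }
    r_obs <- slope_sign * sqrt(max(0, 1 - sse_lin[1] / sse_mean[1]))
    p <- NA_real_
    if (perms > 0) {
      r_perm <- vapply(seq_len(perms) + 1L, stat, numeric(1))
      p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (perms + 1)
    }
    tibble(r = r_obs, p_value = p, n = n, folds = folds, reps = reps)
  })
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject ANOVA for a complete participant x condition table,
#' computed from sums of squares: condition and participant effects are
#' removed from the total, the remainder is the error term, and
#' `F = MS_condition / MS_error` with `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom.
#'
#' @param values Data frame with columns `participant`, `condition`,
#'   `value`; every participant must appear in every condition exactly once.
#' @return A one-row tibble: `f_stat`, `df_num`, `df_den`, `p_value`,
#'   `ss_condition`, `ss_error`.
#' @export
rm_anova <- function(values) {
  need <- c("participant", "condition", "value")
  if (!all(need %in% names(values))) {
    abort("`values` needs columns participant, condition, value.")
  }
  tab <- table(values$participant, values$condition)
  if (any(tab != 1)) abort("design must be complete: one value per cell.")
  k <- length(unique(values$condition))
  n <- length(unique(values$participant))
  grand <- mean(values$value)
  cond_means <- tapply(values$value, values$condition, mean)
  subj_means <- tapply(values$value, values$participant, mean)
  ss_total <- sum((values$value - grand)^2)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_err <- ss_total - ss_cond - ss_subj
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  # a condition effect of exactly zero is F = 0 even when the error term
  # also vanishes (constant values within participant)
  fstat <- if (ss_cond == 0) 0 else (ss_cond / df1) / (ss_err / df2)
  tibble(f_stat = fstat, df_num = df1, df_den = df2,
         p_value = pf(fstat, df1, df2, lower.tail = FALSE),
         ss_condition = ss_cond, ss_error = ss_err)
}

#' Holm-Bonferroni step-down correction
#'
#' @param p_values Raw p-values.
#' @param alpha Family-wise error level.
#' @return A tibble: `p`, `p_adjusted` (Holm), `reject`.
#' @examples
#' holm_bonferroni(c(0.01, 0.02, 0.04))
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1)) abort("p-values must be in [0, 1].")
  adj <- stats::p.adjust(p_values, method = "holm")
  tibble(p = p_values, p_adjusted = adj, reject = adj <= alpha)
}

#' Hit proportions over each exploitation horizon
#'
#' @param outcomes Classified outcomes of the harvest trials, in order.
#' @param cfg [exp2_config()].
#' @param include_faults Keep faults in the denominator (the default).
#' @return A tibble: `horizon`, `hit_prop`.
#' @export
horizon_hit_proportions <- function(outcomes, cfg = exp2_config(),
                                    include_faults = TRUE) {
  purrr::map_dfr(cfg$horizons, function(H) {
    o <- outcomes[seq_len(min(H, length(outcomes)))]
    if (!include_faults) o <- o[o != "fault"]
    tibble(horizon = H, hit_prop = mean(o == "hit"))
  })
}
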