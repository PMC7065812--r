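#' Heaviside reward indicator
#'
#' A trial is rewarded when the endpoint error fits inside the target:
#' `H[r - e] = 1` if `r - e >= 0`, else `0`. The boundary case (error exactly
#' equal to the radius) counts as a hit.
#'
#' @param radius Target radius (mm), positive. Recycled against `error`.
#' @param error Endpoint error (mm), non-negative.
#' @return Integer vector of 0/1.
#' @examples
#' heaviside_reward(64, c(64, 64.001)) # 1 0
#' @export
heaviside_reward <- function(radius, error) {
  if (any(radius <= 0)) abort("`radius` must be positive.")
  if (any(error < 0)) abort("`error` must be non-negative.")
  as.integer(radius - error >= 0)
}

#' Lead-lag window policy parameters
#'
#' `lag` past trials and `lead` future trials define the window over which a
#' candidate target is valued at each decision point.
#'
#' @param lead Number of future trials considered (>= 0).
#' @param lag Number of past trials considered (>= 0).
#' @return A list of class `ll_policy`.
#' @examples
#' policy_params(lead = 18, lag = 14)
#' @export
policy_params <- function(lead, lag) {
  lead <- as.integer(lead); lag <- as.integer(lag)
  if (lead < 0L || lag < 0L) abort("`lead` and `lag` must be >= 0.")
  structure(list(lead = lead, lag = lag), class = "ll_policy")
}

#' @export
print.ll_policy <- function(x, ...) {
  cat("<ll_policy> lead =", x$lead, "lag =", x$lag, "\n")
  invisible(x)
}

# n x n_targets 0/1 matrix: does trial k's error fit target i (with margin)?
hit_matrix <- function(errors, targets) {
  outer(errors, targets$radii + targets$hit_margin, `<=`) * 1L
}

# (n+1) x n_targets cumulative hit counts, zero row prepended so that
# window sums are cs[hi + 1, ] - cs[lo, ]
cum_hits <- function(errors, targets) {
  hm <- hit_matrix(errors, targets)
  rbind(0L, apply(hm, 2L, cumsum))
}

window_bounds <- function(j, policy, cfg) {
  centre <- cfg$block_size * j
  c(lo = max(1L, centre - policy$lag),
    hi = min(centre + policy$lead, cfg$n_trials))
}

#' Windowed value of candidate targets at a decision point
#'
#' At decision `j` (taken on trial `5j`), the value of target `i` is the
#' points it would have earned over the clamped window of the `lag` previous
#' and `lead` future trials, the decision trial included:
#' `V(i, j) = sum_{k = max(1, 5j - lag)}^{min(5j + lead, 200)} i * H[r_i - e_k]`.
#'
#' @param i Target index (1..6), possibly a vector.
#' @param j Decision index (1..39).
#' @param policy [policy_params()].
#' @param errors Per-trial endpoint errors (mm), length `cfg$n_trials`.
#' @param targets [target_set()].
#' @param cfg [experiment_config()].
#' @return Numeric vector of window values, one per element of `i`.
#' @examples
#' cfg <- experiment_config(n_trials = 5, block_size = 5)
#' # single-block toy: no decisions, so use the full default below
#' @export
window_value <- function(i, j, policy, errors, targets, cfg = experiment_config()) {
  check_errors(errors, cfg)
  if (j < 1L || j > cfg$n_decisions) {
    abort(paste0("`j` must be in 1..", cfg$n_decisions, "."))
  }
  if (any(i < 1L | i > targets$n)) abort("`i` out of target range.")
  cs <- cum_hits(errors, targets)
  b <- window_bounds(j, policy, cfg)
  hits <- cs[b["hi"] + 1L, i] - cs[b["lo"], i]
  targets$values[i] * hits
}

check_errors <- function(errors, cfg) {
  if (length(errors) != cfg$n_trials) {
    abort(paste0("`errors` must have length ", cfg$n_trials, "."))
  }
  if (any(!is.finite(errors)) || any(errors < 0)) {
    abort("`errors` must be finite and non-negative.")
  }
  invisible(errors)
}

#' Constrained windowed argmax target selection
#'
#' Returns the target `q* = argmax_{q >= current} V(q, j, lag, lead)`:
#' among targets no larger than the currently selected one, the one whose
#' window value is maximal. Ties are broken toward the smallest admissible
#' index (the largest target), so with no evidence the model stays put.
#'
#' @inheritParams window_value
#' @param current Currently selected target index.
#' @return The selected target index.
#' @export
select_target <- function(current, j, policy, errors, targets,
                          cfg = experiment_config()) {
  if (current < 1L || current > targets$n) abort("`current` out of range.")
  cand <- current:targets$n
  v <- window_value(cand, j, policy, errors, targets, cfg)
  cand[which.max(v)]
}

#' Roll out a lead-lag policy over a session
#'
#' Starting from the largest target (forced for block 1), applies
#' [select_target()] sequentially at each of the `n_decisions` decision
#' points, threading the never-larger constraint: the admissible set at each
#' decision is bounded below by the previously selected index. Realized
#' points are computed by [score_points()].
#'
#' @inheritParams window_value
#' @param scoring_targets Target set used to score realized points; defaults
#'   to `targets` (so hits use the same margin as valuation).
#' @return A list of class `ll_rollout`: `choices` (length `n_decisions`),
#'   `block_targets` (length `n_blocks`, block 1 forced to target 1),
#'   `points`, and `policy`.
#' @examples
#' cfg <- experiment_config()
#' err <- rep(20, 200) # every throw lands 20 mm out: all targets hit
#' ro <- rollout_policy(err, policy_params(0, 5), target_set(), cfg)
#' ro$choices[1] # jumps straight to target 6
#' @export
rollout_policy <- function(errors, policy, targets, cfg = experiment_config(),
                           scoring_targets = targets) {
  check_errors(errors, cfg)
  cs <- cum_hits(errors, targets)
  vals <- targets$values
  nt <- targets$n
  choices <- integer(cfg$n_decisions)
  current <- 1L
  for (j in seq_len(cfg$n_decisions)) {
    centre <- cfg$block_size * j
    lo <- max(1L, centre - policy$lag)
    hi <- min(centre + policy$lead, cfg$n_trials)
    cand <- current:nt
    v <- vals[cand] * (cs[hi + 1L, cand] - cs[lo, cand])
    current <- cand[which.max(v)]
    choices[j] <- current
  }
  block_targets <- c(1L, choices)
  structure(
    list(choices = choices,
         block_targets = block_targets,
         points = score_points(errors, choices, scoring_targets, cfg),
         policy = policy),
    class = "ll_rollout"
  )
}

#' @export
print.ll_rollout <- function(x, ...) {
  cat("<ll_rollout> lead =", x$policy$lead, "lag =", x$policy$lag,
      "| points =", x$points, "\n")
  cat("choices:", paste(x$choices, collapse = " "), "\n")
  invisible(x)
}

#' Score a full choice sequence against per-trial errors
#'
#' Total points over the session: block 1 is played on target 1 (forced);
#' block `b + 1` is played on `choices[b]`. Each trial in a block earns the
#' block target's value when the error fits within `radius + hit_margin`.
#'
#' @inheritParams window_value
#' @param choices Target index per decision (`n_decisions` long),
#'   non-decreasing.
#' @return Total points (numeric scalar).
#' @export
score_points <- function(errors, choices, targets, cfg = experiment_config()) {
  check_errors(errors, cfg)
  if (length(choices) != cfg$n_decisions) {
    abort(paste0("`choices` must have length ", cfg$n_decisions, "."))
  }
  if (is.unsorted(choices)) {
    abort("`choices` must be non-decreasing (targets never grow).")
  }
  block_targets <- c(1L, as.integer(choices))
  cs <- cum_hits(errors, targets)
  bs <- cfg$block_size
  total <- 0
  for (b in seq_len(cfg$n_blocks)) {
    i <- block_targets[b]
    lo <- (b - 1L) * bs + 1L
    hi <- b * bs
    total <- total + targets$values[i] * (cs[hi + 1L, i] - cs[lo, i])
  }
  total
}

# per-(block, target) points table: entry [b, i] is the points earned in
# block b if target i were active. Used by the solvers.
block_points_table <- function(errors, targets, cfg = experiment_config()) {
  check_errors(errors, cfg)
  cs <- cum_hits(errors, targets)
  bs <- cfg$block_size
  idx_hi <- seq_len(cfg$n_blocks) * bs
  hits <- cs[idx_hi + 1L, , drop = FALSE] - cs[idx_hi - bs + 1L, , drop = FALSE]
  sweep(hits, 2L, targets$values, `*`)
}
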