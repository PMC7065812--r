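#' Count admissible target-selection scenarios
#'
#' A scenario is a complete sequence of target choices, one per decision
#' point, that never selects a larger target than the current one, i.e. a
#' non-decreasing sequence of `n_decisions` indices over `n_targets` symbols.
#' The count is the stars-and-bars binomial
#' `choose(n_decisions + n_targets - 1, n_targets - 1)`. For the full task
#' (39 decisions, 6 targets) this is 1,086,008; without the never-larger rule
#' it would be `6^39`, about `2.2e30`.
#'
#' @param n_decisions Number of decision points.
#' @param n_targets Number of targets.
#' @return The scenario count (numeric; exact for the task's sizes).
#' @examples
#' count_scenarios(2, 2)  # 3: (1,1) (1,2) (2,2)
#' count_scenarios(39, 6) # 1086008
#' @export
count_scenarios <- function(n_decisions, n_targets) {
  if (n_decisions < 1 || n_targets < 1) abort("arguments must be positive.")
  choose(n_decisions + n_targets - 1, n_targets - 1)
}

#' Globally optimal target sequence by dynamic programming
#'
#' Finds the choice sequence maximizing total points given the session's
#' actual per-trial errors, subject to the task's two constraints: block 1 is
#' played on the largest target, and the target index never decreases in
#' size rank (never a larger target than the current one). Exact via dynamic
#' programming over (block, current target); equivalent to enumerating every
#' admissible scenario. Ties are resolved to the lexicographically smallest
#' index sequence (later switches to smaller targets).
#'
#' @inheritParams window_value
#' @return A list of class `ll_solution`: `choices`, `block_targets`,
#'   `points`, `method = "dp"`.
#' @examples
#' cfg <- experiment_config(n_trials = 10, block_size = 5)
#' err <- c(300, 120, 60, 45, 30, rep(30, 5))
#' global_optimal_dp(err, target_set(), cfg)$points # 34
#' @export
global_optimal_dp <- function(errors, targets, cfg = experiment_config()) {
  bp <- block_points_table(errors, targets, cfg)
  nb <- cfg$n_blocks
  nt <- targets$n
  # G[b, i]: best total over blocks b..nb when the block-b target must be >= i
  G <- matrix(0, nb + 1L, nt)
  best_at <- matrix(0, nb, nt) # best total when block b plays exactly target i
  for (b in nb:1) {
    tot <- bp[b, ] + G[b + 1L, ]
    best_at[b, ] <- tot
    G[b, ] <- rev(cummax(rev(tot)))
  }
  choices <- integer(cfg$n_decisions)
  prev <- 1L
  for (b in 2L:nb) {
    cand <- prev:nt
    tot <- best_at[b, cand]
    prev <- cand[which.max(tot)] # first max = smallest index
    choices[b - 1L] <- prev
  }
  new_solution(choices, errors, targets, cfg, method = "dp")
}

new_solution <- function(choices, errors, targets, cfg, method) {
  structure(
    list(choices = choices,
         block_targets = c(1L, choices),
         points = score_points(errors, choices, targets, cfg),
         method = method),
    class = "ll_solution"
  )
}

#' @export
print.ll_solution <- function(x, ...) {
  cat("<ll_solution> [", x$method, "] points =", x$points, "\n")
  cat("choices:", paste(x$choices, collapse = " "), "\n")
  invisible(x)
}

#' Globally optimal target sequence by exhaustive enumeration
#'
#' Brute-force counterpart of [global_optimal_dp()]: walks every admissible
#' non-decreasing choice sequence in lexicographic order and keeps the best
#' total (first encountered on ties, hence lexicographically smallest).
#' Retained as an independent oracle for the dynamic program; practical for
#' truncated sessions (the full task has 1,086,008 scenarios).
#'
#' @inheritParams window_value
#' @return A list of class `ll_solution` with the extra field `n_visited`,
#'   the number of sequences enumerated (equals [count_scenarios()]).
#' @export
global_optimal_bruteforce <- function(errors, targets, cfg = experiment_config()) {
  bp <- block_points_table(errors, targets, cfg)
  nd <- cfg$n_decisions
  nt <- targets$n
  base <- bp[1L, 1L]
  best_total <- -Inf
  best_choices <- integer(nd)
  n_visited <- 0
  # depth-first walk in lexicographic order, partial sums carried down
  rec <- function(d, lo, acc, prefix) {
    if (d > nd) {
      n_visited <<- n_visited + 1
      if (acc > best_total) {
        best_total <<- acc
        best_choices <<- prefix
      }
      return(invisible())
    }
    for (q in lo:nt) {
      rec(d + 1L, q, acc + bp[d + 1L, q], c(prefix, q))
    }
  }
  rec(1L, 1L, base, integer(0))
  sol <- new_solution(best_choices, errors, targets, cfg, method = "bruteforce")
  sol$n_visited <- n_visited
  sol
}

#' Exact distribution of scenario totals
#'
#' Computes, for a session's errors, the number of admissible scenarios
#' achieving each possible point total, by a convolution dynamic program over
#' (block, current target, running total). From this exact histogram the
#' rank, percentile, and z-score of any particular scenario (e.g. a
#' participant's actual choices) follow without materializing the million-odd
#' sequences.
#'
#' @inheritParams window_value
#' @return A list of class `ll_scenario_dist`: `histogram` (tibble with
#'   `total`, `n_scenarios`), `n_total`, `mean`, `sd`, `min`, `max`.
#' @export
scenario_distribution <- function(errors, targets, cfg = experiment_config()) {
  bp <- block_points_table(errors, targets, cfg)
  if (any(abs(bp - round(bp)) > 1e-9)) {
    abort("scenario distribution requires integer point values.")
  }
  bp <- round(bp)
  nb <- cfg$n_blocks
  nt <- targets$n
  smax <- sum(apply(bp, 1L, max))
  # D[i, s + 1]: number of partial sequences with current target i, total s
  D <- matrix(0, nt, smax + 1L)
  D[1L, bp[1L, 1L] + 1L] <- 1 # block 1 forced on target 1
  for (b in 2L:nb) {
    Dc <- apply(D, 2L, cumsum) # row i: sequences with current target <= i
    if (nt == 1L) Dc <- matrix(Dc, nrow = 1L)
    Dn <- matrix(0, nt, smax + 1L)
    for (i in seq_len(nt)) {
      s <- bp[b, i]
      n <- smax + 1L - s
      Dn[i, (s + 1L):(smax + 1L)] <- Dc[i, 1L:n]
    }
    D <- Dn
  }
  counts <- colSums(D)
  keep <- counts > 0
  totals <- which(keep) - 1L
  n <- counts[keep]
  N <- sum(n)
  mu <- sum(totals * n) / N
  sdev <- sqrt(sum((totals - mu)^2 * n) / N) # population SD over all scenarios
  structure(
    list(histogram = tibble(total = totals, n_scenarios = n),
         n_total = N, mean = mu, sd = sdev,
         min = min(totals), max = max(totals)),
    class = "ll_scenario_dist"
  )
}

#' @export
print.ll_scenario_dist <- function(x, ...) {
  cat("<ll_scenario_dist>", format(x$n_total, big.mark = ","),
      "scenarios; totals", x$min, "-", x$max,
      sprintf("(mean %.1f, sd %.1f)\n", x$mean, x$sd))
  invisible(x)
}

#' Rank a scenario within the distribution of all scenarios
#'
#' @param dist A [scenario_distribution()] result.
#' @param points The scenario's total points.
#' @return A one-row tibble: `points`, `rank` (1 = best, ties share the top
#'   rank), `percentile` (share of scenarios scoring `<=` this one, in
#'   percent), `zscore`.
#' @export
scenario_rank <- function(dist, points) {
  h <- dist$histogram
  n_greater <- sum(h$n_scenarios[h$total > points])
  n_leq <- sum(h$n_scenarios[h$total <= points])
  tibble(
    points = points,
    rank = n_greater + 1,
    percentile = 100 * n_leq / dist$n_total,
    zscore = (points - dist$mean) / dist$sd
  )
}

#' Best constant lead-lag policy for realized reward
#'
#' Grid search for the (lead, lag) window whose sequential rollout
#' ([rollout_policy()]) earns the most points on the session's errors — the
#' best decision rule that, unlike the global optimum, only looks at a fixed
#' local window around each decision point. Ties go to the smaller lead,
#' then the smaller lag.
#'
#' @inheritParams window_value
#' @param lead_range,lag_range Integer vectors of window lengths to search.
#' @param keep_grid If `TRUE`, the full evaluation grid is returned.
#' @return A list of class `ll_local_opt`: `policy`, `points`, `choices`,
#'   and optionally `grid` (tibble `lead`, `lag`, `points`).
#' @export
local_optimal_search <- function(errors, targets, cfg = experiment_config(),
                                 lead_range = 0:(cfg$n_trials - cfg$block_size),
                                 lag_range = 0:(cfg$n_trials - 1),
                                 keep_grid = FALSE) {
  if (length(lead_range) == 0 || length(lag_range) == 0) {
    abort("`lead_range` and `lag_range` must be non-empty.")
  }
  check_errors(errors, cfg)
  cs <- cum_hits(errors, targets)
  bp <- block_points_table(errors, targets, cfg)
  base <- bp[1L, 1L]
  lead_range <- sort(unique(as.integer(lead_range)))
  lag_range <- sort(unique(as.integer(lag_range)))
  best <- list(points = -Inf)
  grid <- if (keep_grid) {
    tidyr::expand_grid(lead = lead_range, lag = lag_range)
  }
  grid_points <- if (keep_grid) numeric(nrow(grid))
  gi <- 0L
  for (lead in lead_range) {
    for (lag in lag_range) {
      ch <- rollout_choices(cs, targets, cfg, lead, lag)
      pts <- base + sum(bp[cbind(2:cfg$n_blocks, ch)])
      if (keep_grid) {
        gi <- gi + 1L
        grid_points[gi] <- pts
      }
      if (pts > best$points) {
        best <- list(policy = policy_params(lead, lag), points = pts,
                     choices = ch)
      }
    }
  }
  if (keep_grid) {
    grid$points <- grid_points
    grid <- dplyr::arrange(grid, .data$lead, .data$lag)
  }
  structure(c(best, list(grid = grid)), class = "ll_local_opt")
}

# rollout inner loop sharing precomputed cumulative hit counts
rollout_choices <- function(cs, targets, cfg, lead, lag) {
  vals <- targets$values
  nt <- targets$n
  nd <- cfg$n_decisions
  bs <- cfg$block_size
  n <- cfg$n_trials
  choices <- integer(nd)
  current <- 1L
  for (j in seq_len(nd)) {
    centre <- bs * j
    lo <- max(1L, centre - lag)
    hi <- min(centre + lead, n)
    cand <- current:nt
    v <- vals[cand] * (cs[hi + 1L, cand] - cs[lo, cand])
    current <- cand[which.max(v)]
    choices[j] <- current
  }
  choices
}

#' @export
print.ll_local_opt <- function(x, ...) {
  cat("<ll_local_opt> lead =", x$policy$lead, "lag =", x$policy$lag,
      "| points =", x$points, "\n")
  invisible(x)
}

#' Minimax design of target radii from pilot error data
#'
#' Reconstruction of the target-size design procedure: choose `n_targets`
#' radii so that, when each pilot participant's globally optimal selections
#' are computed for the candidate set, no single target is occupied for too
#' many trials — i.e. minimize (over candidate sets) the maximum per-target
#' occupancy, pooled over pilot participants, subject to the pooled hit rate
#' under optimal occupancy staying above `hit_rate_floor`. The search is a
#' seeded random sample of decreasing radius sets from an integer grid,
#' refined by greedy coordinate descent.
#'
#' @param pilot_errors List of per-trial error vectors (one per pilot
#'   participant), each `cfg$n_trials` long.
#' @param n_targets Number of radii to choose.
#' @param hit_rate_floor Minimum admissible pooled hit rate.
#' @param cfg [experiment_config()].
#' @param radius_grid Candidate radii (mm).
#' @param n_random Random candidate sets drawn before refinement.
#' @param seed Integer seed for the random search.
#' @return A list of class `ll_design`: `radii`, `objective` (max pooled
#'   occupancy, in trials), `hit_rate`, `feasible`, `occupancy` (tibble).
#'   If no candidate satisfies the floor, `feasible` is `FALSE` and the best
#'   infeasible set is returned for inspection.
#' @export
design_targets_minimax <- function(pilot_errors, n_targets = 6,
                                   hit_rate_floor = 0.5,
                                   cfg = experiment_config(),
                                   radius_grid = 10:250,
                                   n_random = 100, seed = 1L) {
  if (!length(pilot_errors)) abort("`pilot_errors` must be non-empty.")
  purrr::walk(pilot_errors, check_errors, cfg = cfg)
  radius_grid <- sort(unique(as.numeric(radius_grid)), decreasing = TRUE)
  if (length(radius_grid) < n_targets) abort("radius grid too small.")

  evaluate <- function(radii) {
    ts <- target_set(radii = radii, values = seq_len(n_targets))
    occ <- numeric(n_targets)
    hits <- 0
    for (err in pilot_errors) {
      sol <- global_optimal_dp(err, ts, cfg)
      tab <- tabulate(sol$block_targets, nbins = n_targets) * cfg$block_size
      occ <- occ + tab
      hm <- hit_matrix(err, ts)
      blk <- rep(sol$block_targets, each = cfg$block_size)
      hits <- hits + sum(hm[cbind(seq_along(err), blk)])
    }
    list(objective = max(occ), occupancy = occ,
         hit_rate = hits / (length(pilot_errors) * cfg$n_trials))
  }

  draw_set <- function() sort(sample(radius_grid, n_targets), decreasing = TRUE)

  better <- function(a, b, radii_a = NULL, radii_b = NULL) {
    # feasibility first, then objective; objective ties go to the smaller
    # radii (harder targets are worth more points at equal balance)
    if (is.null(b)) return(TRUE)
    fa <- a$hit_rate > hit_rate_floor
    fb <- b$hit_rate > hit_rate_floor
    if (fa != fb) return(fa)
    if (a$objective != b$objective) return(a$objective < b$objective)
    !is.null(radii_a) && !is.null(radii_b) && sum(radii_a) < sum(radii_b)
  }

  withr_seed(seed, {
    best <- NULL
    best_radii <- NULL
    # quantile-seeded candidate: radii near the error quantiles give
    # near-balanced occupancy by construction, a strong starting point
    pooled_err <- sort(unlist(pilot_errors))
    q <- stats::quantile(pooled_err, probs = seq_len(n_targets) / n_targets,
                         type = 1, names = FALSE)
    snap_up <- function(v) {
      vapply(v, function(x) {
        cand <- radius_grid[radius_grid >= x]
        if (length(cand)) min(cand) else max(radius_grid)
      }, numeric(1))
    }
    q_radii <- sort(unique(snap_up(rev(q))), decreasing = TRUE)
    if (length(q_radii) == n_targets) {
      best <- evaluate(q_radii)
      best_radii <- q_radii
    }
    for (k in seq_len(n_random)) {
      radii <- draw_set()
      ev <- evaluate(radii)
      if (better(ev, best, radii, best_radii)) {
        best <- ev
        best_radii <- radii
      }
    }
    # greedy coordinate refinement over the grid
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (pos in seq_len(n_targets)) {
        upper <- if (pos == 1) Inf else best_radii[pos - 1]
        lower <- if (pos == n_targets) -Inf else best_radii[pos + 1]
        for (r in radius_grid[radius_grid < upper & radius_grid > lower]) {
          cand <- best_radii
          cand[pos] <- r
          ev <- evaluate(cand)
          if (better(ev, best, cand, best_radii)) {
            best <- ev
            best_radii <- cand
            improved <- TRUE
          }
        }
      }
    }
    structure(
      list(radii = best_radii, objective = best$objective,
           hit_rate = best$hit_rate,
           feasible = best$hit_rate > hit_rate_floor,
           occupancy = tibble(target = seq_len(n_targets),
                              radius = best_radii,
                              trials = best$occupancy)),
      class = "ll_design"
    )
  })
}

#' @export
print.ll_design <- function(x, ...) {
  cat("<ll_design> radii (mm):", paste(x$radii, collapse = ", "), "\n")
  cat("max occupancy:", x$objective, "trials | pooled hit rate:",
      sprintf("%.2f", x$hit_rate),
      if (x$feasible) "(feasible)" else "(INFEASIBLE)", "\n")
  invisible(x)
}

# evaluate `code` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}
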