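#' Experiment-1 session configuration
#'
#' Trial-count bookkeeping for the throwing task: 200 trials in blocks of 5,
#' with a target-selection decision after every block except the last, giving
#' 39 decision points. Points convert to money at $0.02 per point.
#'
#' @param n_trials Total throwing trials per session.
#' @param block_size Trials per block between decisions.
#' @param point_value Dollars earned per point.
#' @param target_distance Distance from launch position to target centre (mm).
#' @return A list of class `ll_config` with fields `n_trials`, `block_size`,
#'   `n_decisions`, `n_blocks`, `point_value`, `target_distance`.
#' @examples
#' cfg <- experiment_config()
#' cfg$n_decisions # 39
#' @export
experiment_config <- function(n_trials = 200L, block_size = 5L,
                              point_value = 0.02, target_distance = 300) {
  n_trials <- as.integer(n_trials)
  block_size <- as.integer(block_size)
  if (n_trials <= 0L || block_size <= 0L) {
    abort("`n_trials` and `block_size` must be positive.")
  }
  if (n_trials %% block_size != 0L) {
    abort("`n_trials` must be a multiple of `block_size`.")
  }
  n_blocks <- n_trials %/% block_size
  structure(
    list(
      n_trials = n_trials,
      block_size = block_size,
      n_blocks = n_blocks,
      n_decisions = n_blocks - 1L,
      point_value = point_value,
      target_distance = target_distance
    ),
    class = "ll_config"
  )
}

#' @export
print.ll_config <- function(x, ...) {
  cat("<ll_config> ", x$n_trials, " trials in blocks of ", x$block_size,
      " (", x$n_decisions, " decisions)\n", sep = "")
  invisible(x)
}

#' The six-target set of the throwing task
#'
#' Targets are indexed 1..6 by decreasing radius; the point value of target
#' `i` is `i`, so smaller targets are worth more. `hit_margin` widens the hit
#' criterion: a trial counts as a hit when
#' `error <= radius + hit_margin`. The model equations use a margin of 0
#' (the puck centre must land inside the target radius); the task as
#' experienced by participants granted a hit when any part of the 5 mm-radius
#' puck came within 1 mm of the target edge, i.e. a margin of 6 mm.
#'
#' @param radii Target radii in mm, strictly decreasing.
#' @param values Point values, defaults to `seq_along(radii)`.
#' @param hit_margin Extra distance (mm) added to each radius when scoring
#'   hits. Use `0` for the model convention, `6` for the task-display
#'   convention.
#' @return A list of class `ll_targets` with fields `radii`, `values`,
#'   `hit_margin`, `n`.
#' @examples
#' target_set()$radii
#' target_set(hit_margin = 6)
#' @export
target_set <- function(radii = c(208, 104, 64, 48, 38, 32),
                       values = seq_along(radii),
                       hit_margin = 0) {
  if (any(diff(radii) >= 0)) abort("`radii` must be strictly decreasing.")
  if (length(values) != length(radii)) {
    abort("`values` must match `radii` in length.")
  }
  if (hit_margin < 0) abort("`hit_margin` must be >= 0.")
  structure(
    list(radii = as.numeric(radii), values = as.numeric(values),
         hit_margin = as.numeric(hit_margin), n = length(radii)),
    class = "ll_targets"
  )
}

#' @export
print.ll_targets <- function(x, ...) {
  cat("<ll_targets> radii (mm):", paste(x$radii, collapse = ", "),
      "| values:", paste(x$values, collapse = ", "),
      "| hit margin:", x$hit_margin, "mm\n")
  invisible(x)
}

#' Experiment-2 (visuomotor rotation) configuration
#'
#' Geometry and classification constants for the reaching task: a 45 deg
#' cursor rotation, a 10 mm-radius target and 5 mm-radius cursor at a 100 mm
#' reach amplitude, a 350 ms reaction-time fault criterion, and three
#' exploitation horizons (24, 150, 216 harvest trials). Reward schedules are
#' hit:miss point splits summing to 100, selectable from 60:40 to 100:0 with
#' the slider starting at 80:20.
#'
#' @param rotation Rotation of the viewed cursor, degrees.
#' @param rt_fault Reaction-time fault threshold, ms.
#' @param target_radius,cursor_radius,amplitude Geometry, mm.
#' @param horizons Exploitation horizons in harvest trials.
#' @param hit_value_range Allowed hit values (points for a hit).
#' @param schedule_sum Hit value + miss value.
#' @param default_schedule Initial slider hit value.
#' @param n_initial_learning Rotated trials before schedule selection.
#' @param n_baseline_practice,n_baseline_harvest Baseline phase lengths.
#' @return A list of class `ll_exp2_config`.
#' @export
exp2_config <- function(rotation = 45, rt_fault = 350,
                        target_radius = 10, cursor_radius = 5,
                        amplitude = 100,
                        horizons = c(24L, 150L, 216L),
                        hit_value_range = c(60L, 100L),
                        schedule_sum = 100L,
                        default_schedule = 80L,
                        n_initial_learning = 30L,
                        n_baseline_practice = 30L,
                        n_baseline_harvest = 102L) {
  if (is.unsorted(horizons, strictly = TRUE)) {
    abort("`horizons` must be strictly increasing.")
  }
  if (hit_value_range[1] >= hit_value_range[2]) {
    abort("`hit_value_range` must be an increasing pair.")
  }
  structure(
    list(rotation = rotation, rt_fault = rt_fault,
         target_radius = target_radius, cursor_radius = cursor_radius,
         amplitude = amplitude, horizons = as.integer(horizons),
         hit_value_range = as.integer(hit_value_range),
         schedule_sum = as.integer(schedule_sum),
         default_schedule = as.integer(default_schedule),
         n_initial_learning = as.integer(n_initial_learning),
         n_baseline_practice = as.integer(n_baseline_practice),
         n_baseline_harvest = as.integer(n_baseline_harvest)),
    class = "ll_exp2_config"
  )
}

#' @export
print.ll_exp2_config <- function(x, ...) {
  cat("<ll_exp2_config> rotation", x$rotation, "deg; RT fault >", x$rt_fault,
      "ms; horizons", paste(x$horizons, collapse = "/"), "trials\n")
  invisible(x)
}
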