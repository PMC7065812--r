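#' Write throwing sessions in the package CSV dialect
#'
#' Two UTF-8 comma-separated files with header rows: a trials table (one
#' row per trial: `participant_id`, `trial`, `final_x`, `final_y`, `error`,
#' `target_index`, `hit`) and a companion choices table (one row per
#' decision: `participant_id`, `decision`, `target_index`). Coordinates are
#' relative to the target centre with y positive up-screen (overshoot
#' positive); `hit` is derived from the error and the active target's
#' radius under `targets$hit_margin`.
#'
#' @param sessions List of throw sessions (with `choices` attached).
#' @param trials_path,choices_path Output file paths.
#' @param targets [target_set()] (sets the hit convention of the derived
#'   `hit` column).
#' @param cfg [experiment_config()].
#' @return Invisibly, the two paths.
#' @export
write_throw_sessions <- function(sessions, trials_path, choices_path,
                                 targets = target_set(),
                                 cfg = experiment_config()) {
  sessions <- as_throw_session_list(sessions)
  trials <- purrr::map_dfr(sessions, function(s) {
    block_targets <- c(1L, as.integer(s$choices))
    trial_target <- rep(block_targets, each = cfg$block_size)
    tibble(
      participant_id = s$participant_id,
      trial = seq_along(s$errors),
      final_x = s$final_x, final_y = s$final_y, error = s$errors,
      target_index = trial_target,
      hit = hit_matrix(s$errors, targets)[cbind(seq_along(s$errors),
                                                trial_target)] == 1L
    )
  })
  choices <- purrr::map_dfr(sessions, function(s) {
    tibble(participant_id = s$participant_id,
           decision = seq_along(s$choices),
           target_index = as.integer(s$choices))
  })
  readr::write_csv(trials, trials_path)
  readr::write_csv(choices, choices_path)
  invisible(c(trials_path, choices_path))
}

throw_trials_cols <- c("participant_id", "trial", "final_x", "final_y",
                       "error", "target_index", "hit")
throw_choices_cols <- c("participant_id", "decision", "target_index")
reach_trials_cols <- c("participant_id", "trial", "phase", "angular_error",
                       "reaction_time", "outcome")
reach_selections_cols <- c("participant_id", "horizon", "hit_value")

check_header <- function(df, expected, path) {
  if (!identical(names(df), expected)) {
    abort(paste0("unexpected columns in ", path, ": expected ",
                 paste(expected, collapse = ", ")))
  }
}

#' Read throwing sessions from the package CSV dialect
#'
#' @param trials_path,choices_path Files written by
#'   [write_throw_sessions()].
#' @return A list of `ll_throw_session` objects.
#' @export
read_throw_sessions <- function(trials_path, choices_path) {
  trials <- readr::read_csv(trials_path, show_col_types = FALSE)
  choices <- readr::read_csv(choices_path, show_col_types = FALSE)
  check_header(trials, throw_trials_cols, trials_path)
  check_header(choices, throw_choices_cols, choices_path)
  ids <- unique(trials$participant_id)
  purrr::map(ids, function(id) {
    tr <- dplyr::arrange(dplyr::filter(trials, .data$participant_id == id),
                         .data$trial)
    ch <- dplyr::arrange(dplyr::filter(choices, .data$participant_id == id),
                         .data$decision)
    structure(
      list(participant_id = id, errors = tr$error,
           final_x = tr$final_x, final_y = tr$final_y,
           choices = as.integer(ch$target_index)),
      class = "ll_throw_session"
    )
  })
}

#' Write reach sessions in the package CSV dialect
#'
#' A trials table (`participant_id`, `trial`, `phase`, `angular_error`,
#' `reaction_time`, `outcome`) and a selections table (`participant_id`,
#' `horizon` — a horizon length in trials, or `"baseline"` —, `hit_value`).
#'
#' @param sessions List of `ll_reach_session` objects.
#' @param trials_path,selections_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_reach_sessions <- function(sessions, trials_path, selections_path) {
  trials <- purrr::map_dfr(sessions, function(s) {
    dplyr::mutate(s$trials, participant_id = s$participant_id, .before = 1)
  })
  selections <- purrr::map_dfr(sessions, function(s) {
    tibble(
      participant_id = s$participant_id,
      horizon = c(names(s$selected_hit_values), "baseline"),
      hit_value = c(unname(s$selected_hit_values), s$baseline_hit_value)
    )
  })
  readr::write_csv(trials, trials_path)
  readr::write_csv(selections, selections_path)
  invisible(c(trials_path, selections_path))
}

#' Read reach sessions from the package CSV dialect
#'
#' @param trials_path,selections_path Files written by
#'   [write_reach_sessions()].
#' @return A list of `ll_reach_session` objects.
#' @export
read_reach_sessions <- function(trials_path, selections_path) {
  trials <- readr::read_csv(trials_path, show_col_types = FALSE)
  selections <- readr::read_csv(
    selections_path, show_col_types = FALSE,
    col_types = readr::cols(horizon = readr::col_character())
  )
  check_header(trials, reach_trials_cols, trials_path)
  check_header(selections, reach_selections_cols, selections_path)
  ids <- unique(trials$participant_id)
  purrr::map(ids, function(id) {
    tr <- dplyr::arrange(dplyr::filter(trials, .data$participant_id == id),
                         .data$trial)
    sel <- dplyr::filter(selections, .data$participant_id == id)
    base <- sel$hit_value[sel$horizon == "baseline"]
    hor <- dplyr::filter(sel, .data$horizon != "baseline")
    structure(
      list(participant_id = id,
           trials = dplyr::select(tr, -"participant_id"),
           selected_hit_values = setNames(as.integer(hor$hit_value),
                                          hor$horizon),
           baseline_hit_value = as.integer(base)),
      class = "ll_reach_session"
    )
  })
}

#' Validate a throwing session against the task invariants
#'
#' Checks trial count, choice count and monotonicity (the target never
#' grows), the first-block convention, target-index range, error
#' non-negativity, and — when endpoint coordinates are present — that the
#' resultant error equals the 2-D norm of the components.
#'
#' @param session A throw session (list with `errors`, `choices`, and
#'   optionally `final_x`/`final_y`).
#' @param cfg [experiment_config()].
#' @param targets [target_set()].
#' @param tol Numeric tolerance for the error/coordinate consistency check.
#' @return A tibble of violations (`field`, `message`); zero rows when the
#'   session is valid.
#' @export
validate_throw_session <- function(session, cfg = experiment_config(),
                                   targets = target_set(), tol = 1e-6) {
  v <- list()
  flag <- function(field, message) {
    v[[length(v) + 1L]] <<- tibble(field = field, message = message)
  }
  if (length(session$errors) != cfg$n_trials) {
    flag("errors", paste0("expected ", cfg$n_trials, " trials, found ",
                          length(session$errors)))
  }
  if (any(session$errors < 0, na.rm = TRUE)) {
    flag("errors", "negative movement error")
  }
  ch <- session$choices
  if (is.null(ch)) {
    flag("choices", "no choices attached")
  } else {
    if (length(ch) != cfg$n_decisions) {
      flag("choices", paste0("expected ", cfg$n_decisions,
                             " decisions, found ", length(ch)))
    }
    if (any(ch < 1 | ch > targets$n)) {
      flag("choices", "target index out of range")
    }
    if (is.unsorted(ch)) {
      flag("choices", "choices decrease in index (target grew)")
    }
  }
  if (!is.null(session$final_x) && !is.null(session$final_y) &&
      length(session$final_x) == length(session$errors)) {
    resid <- abs(sqrt(session$final_x^2 + session$final_y^2) - session$errors)
    if (any(resid > tol, na.rm = TRUE)) {
      flag("error", "resultant error does not match endpoint coordinates")
    }
  }
  if (length(v)) dplyr::bind_rows(v) else {
    tibble(field = character(), message = character())
  }
}

#' Read a deposited study container
#'
#' Reads both experiments from a Level-5 MAT container laid out as follows
#' (the layout this package documents and writes for archival round-trips):
#' a struct `exp1` with matrices `errors`, `final_x`, `final_y`
#' (trials x participants) and `choices` (decisions x participants); an
#' optional struct `exploratory` of the same shape; and a struct `exp2`
#' with `angular_error`, `reaction_time` (trials x participants),
#' `selected_hit_values` (horizons x participants), and
#' `baseline_hit_value` (1 x participants). Every session is validated on
#' the way in; violations are reported with participant coordinates.
#'
#' @param path Path to the `.mat` container.
#' @param cfg [experiment_config()].
#' @param exp2_cfg [exp2_config()].
#' @return A list: `throw_sessions`, `exploratory_sessions`,
#'   `reach_sessions`, `validation` (tibble of violations, empty when
#'   clean).
#' @export
read_study_data <- function(path, cfg = experiment_config(),
                            exp2_cfg = exp2_config()) {
  vars <- read_mat(path)
  violations <- list()

  parse_exp1 <- function(grp, label) {
    need <- c("errors", "final_x", "final_y", "choices")
    missing <- setdiff(need, names(grp))
    if (length(missing)) {
      abort(paste0(label, " is missing field(s): ",
                   paste(missing, collapse = ", ")))
    }
    err <- as.matrix(grp$errors)
    n_part <- ncol(err)
    purrr::map(seq_len(n_part), function(i) {
      s <- structure(
        list(participant_id = paste0(label, "_", i),
             errors = err[, i],
             final_x = as.matrix(grp$final_x)[, i],
             final_y = as.matrix(grp$final_y)[, i],
             choices = as.integer(as.matrix(grp$choices)[, i])),
        class = "ll_throw_session"
      )
      rep_v <- validate_throw_session(s, cfg)
      if (nrow(rep_v)) {
        violations[[length(violations) + 1L]] <<-
          dplyr::mutate(rep_v, participant = s$participant_id, .before = 1)
      }
      s
    })
  }

  throw_sessions <- if (!is.null(vars$exp1)) parse_exp1(vars$exp1, "exp1")
  exploratory <- if (!is.null(vars$exploratory)) {
    parse_exp1(vars$exploratory, "exploratory")
  }

  reach_sessions <- NULL
  if (!is.null(vars$exp2)) {
    grp <- vars$exp2
    need <- c("angular_error", "reaction_time", "selected_hit_values",
              "baseline_hit_value")
    missing <- setdiff(need, names(grp))
    if (length(missing)) {
      abort(paste0("exp2 is missing field(s): ",
                   paste(missing, collapse = ", ")))
    }
    ang <- as.matrix(grp$angular_error)
    rt <- as.matrix(grp$reaction_time)
    sel <- as.matrix(grp$selected_hit_values)
    base <- as.numeric(grp$baseline_hit_value)
    phases <- c(rep("baseline_practice", exp2_cfg$n_baseline_practice),
                rep("baseline_harvest", exp2_cfg$n_baseline_harvest),
                rep("initial_learning", exp2_cfg$n_initial_learning),
                rep("harvest", max(exp2_cfg$horizons)))
    if (nrow(ang) != length(phases)) {
      abort(paste0("exp2 angular_error has ", nrow(ang),
                   " trials per participant; expected ", length(phases)))
    }
    reach_sessions <- purrr::map(seq_len(ncol(ang)), function(i) {
      structure(
        list(participant_id = paste0("exp2_", i),
             trials = tibble(
               trial = seq_along(phases), phase = phases,
               angular_error = ang[, i], reaction_time = rt[, i],
               outcome = classify_trials(ang[, i], rt[, i], exp2_cfg)
             ),
             selected_hit_values = setNames(sel[, i],
                                            exp2_cfg$horizons),
             baseline_hit_value = base[i]),
        class = "ll_reach_session"
      )
    })
  }

  list(
    throw_sessions = throw_sessions,
    exploratory_sessions = exploratory,
    reach_sessions = reach_sessions,
    validation = if (length(violations)) dplyr::bind_rows(violations) else {
      tibble(participant = character(), field = character(),
             message = character())
    }
  )
}

# normalize list-of-sessions vs cohort tibble into ll_throw_session lists
as_throw_session_list <- function(sessions) {
  if (is.data.frame(sessions)) {
    purrr::pmap(
      list(sessions$participant, sessions$errors, sessions$final_x,
           sessions$final_y, sessions$choices),
      function(id, er, fx, fy, ch) {
        structure(list(participant_id = id, errors = er, final_x = fx,
                       final_y = fy, choices = ch),
                  class = "ll_throw_session")
      }
    )
  } else if (inherits(sessions, "ll_throw_session")) {
    list(sessions)
  } else {
    sessions
  }
}
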