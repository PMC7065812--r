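#' Damped point-mass puck parameters
#'
#' The virtual puck obeys `F = m a + b v`; the applied force is zeroed once
#' the puck has moved `force_window` mm from its start, after which it
#' coasts and viscosity brings it to rest (closed-form coasting distance
#' `m v / b` from speed `v`). Integration is explicit Euler.
#'
#' @param mass Simulated mass, kg.
#' @param viscosity Force per velocity, N s/m.
#' @param force_window Distance over which force can act, mm.
#' @param target_distance Start-to-target distance, mm.
#' @param timestep Integration step, s.
#' @param stop_speed Resting threshold, mm/s.
#' @return A list of class `ll_puck`.
#' @export
puck_params <- function(mass = 0.010, viscosity = 0.035, force_window = 100,
                        target_distance = 300, timestep = 0.001,
                        stop_speed = 1) {
  if (any(c(mass, viscosity, force_window, target_distance, timestep,
            stop_speed) <= 0)) {
    abort("all puck parameters must be positive.")
  }
  if (force_window >= target_distance) {
    abort("`force_window` must be smaller than `target_distance`.")
  }
  structure(list(mass = mass, viscosity = viscosity,
                 force_window = force_window,
                 target_distance = target_distance,
                 timestep = timestep, stop_speed = stop_speed),
            class = "ll_puck")
}

#' Simulate one puck throw
#'
#' Integrates the damped point mass under an applied force profile. The
#' force follows `impulse` only while the puck is within `force_window` mm
#' of its start; beyond that it is zero and the puck coasts to rest.
#'
#' @param impulse Either a function of time (s) returning the force in N as
#'   `c(fx, fy)`, or a length-2 numeric constant force applied for
#'   `duration` seconds.
#' @param p [puck_params()].
#' @param duration Seconds a constant-force impulse is applied.
#' @param max_time Simulation cap, s; exceeded only if the trajectory fails
#'   to settle (impossible with positive viscosity).
#' @return A list of class `ll_throw`: `endpoint` (mm, c(x, y)),
#'   `window_cross_time` (s; `NA` if the window is never crossed),
#'   `window_cross_speed` (mm/s), `travel` (mm), `trajectory` (tibble
#'   `time`, `x`, `y`, `speed`).
#' @examples
#' thr <- simulate_puck(c(0, 0.08), duration = 0.05)
#' thr$endpoint
#' @export
simulate_puck <- function(impulse, p = puck_params(), duration = 0.05,
                          max_time = 30) {
  force_fn <- if (is.function(impulse)) {
    impulse
  } else {
    if (length(impulse) != 2 || any(!is.finite(impulse))) {
      abort("constant `impulse` must be a finite length-2 force (N).")
    }
    function(t) if (t <= duration) impulse else c(0, 0)
  }
  dt <- p$timestep
  # work in SI internally; positions reported in mm
  win <- p$force_window / 1000
  pos <- c(0, 0)
  vel <- c(0, 0)
  t <- 0
  cross_t <- NA_real_
  cross_speed <- NA_real_
  n_guess <- ceiling(max_time / dt) + 1L
  traj_t <- numeric(n_guess); traj_x <- numeric(n_guess)
  traj_y <- numeric(n_guess); traj_s <- numeric(n_guess)
  i <- 1L
  traj_t[1] <- 0
  repeat {
    d_prev <- sqrt(sum(pos^2))
    v_prev <- sqrt(sum(vel^2))
    inside <- d_prev < win
    f <- if (inside) force_fn(t) else c(0, 0)
    if (any(!is.finite(f))) abort("`impulse` returned a non-finite force.")
    acc <- (f - p$viscosity * vel) / p$mass
    vel <- vel + dt * acc
    pos <- pos + dt * vel
    t <- t + dt
    i <- i + 1L
    traj_t[i] <- t; traj_x[i] <- pos[1] * 1000; traj_y[i] <- pos[2] * 1000
    speed <- sqrt(sum(vel^2))
    traj_s[i] <- speed * 1000
    if (is.na(cross_t) && sqrt(sum(pos^2)) >= win) {
      # linear interpolation to the window crossing within the step
      frac <- (win - d_prev) / max(sqrt(sum(pos^2)) - d_prev, 1e-12)
      cross_t <- t - dt + frac * dt
      cross_speed <- (v_prev + frac * (speed - v_prev)) * 1000
    }
    force_off <- !inside || sqrt(sum(force_fn(t)^2)) == 0
    if (speed * 1000 < p$stop_speed && force_off && t > dt) break
    if (t >= max_time) abort("trajectory did not settle within `max_time`.")
  }
  structure(
    list(endpoint = pos * 1000,
         window_cross_time = cross_t,
         window_cross_speed = cross_speed,
         travel = sqrt(sum(pos^2)) * 1000,
         trajectory = tibble(time = traj_t[seq_len(i)], x = traj_x[seq_len(i)],
                             y = traj_y[seq_len(i)], speed = traj_s[seq_len(i)])),
    class = "ll_throw"
  )
}

#' @export
print.ll_throw <- function(x, ...) {
  cat(sprintf("<ll_throw> endpoint (%.1f, %.1f) mm; travel %.1f mm\n",
              x$endpoint[1], x$endpoint[2], x$travel))
  invisible(x)
}

#' Calibrate a brief impulse to a target throw distance
#'
#' Finds, by bisection, the magnitude of a constant +y force applied for
#' `duration` seconds such that the puck comes to rest at `distance` mm.
#'
#' @param distance Desired resting distance, mm.
#' @param p [puck_params()].
#' @param duration Impulse duration, s (brief, as in a throw).
#' @param interval Force search interval, N.
#' @return The force magnitude in N.
#' @export
calibrate_impulse <- function(distance = 300, p = puck_params(),
                              duration = 0.02, interval = c(1e-4, 5)) {
  f <- stats::uniroot(function(F) {
    simulate_puck(c(0, F), p, duration = duration)$travel - distance
  }, interval = interval, tol = 1e-8)
  f$root
}

#' Learning-curve parameters for the synthetic throwing task
#'
#' The deterministic error curve is `amp * exp(rate * trial) + asymptote`
#' (mm); trial-to-trial jitter around it is Gaussian with a decaying SD
#' `noise_sd_amp * exp(rate * trial) + noise_sd_asymptote`. The endpoint
#' direction carries an overshoot bias in y that decays as
#' `bias_amp_y * exp(bias_rate_y * trial)`, with anisotropic direction
#' noise (`sd_ratio_x` < 1 makes x dispersion smaller than y, as observed
#' in the task). Defaults emulate the throwing experiment: first-block
#' errors near 135 mm decaying to near 35 mm, overshoot bias gone after
#' roughly 20 trials.
#'
#' @param amp,rate,asymptote Error-curve parameters (mm, 1/trial, mm);
#'   `rate` must be negative.
#' @param noise_sd_amp,noise_sd_asymptote Jitter SD curve (mm).
#' @param bias_amp_y,bias_rate_y Overshoot-bias decay.
#' @param sd_ratio_x Ratio of x to y direction dispersion.
#' @return A list of class `ll_curve`.
#' @export
learning_curve_params <- function(amp = 105, rate = -0.025, asymptote = 30,
                                  noise_sd_amp = 25, noise_sd_asymptote = 10,
                                  bias_amp_y = 1.5, bias_rate_y = -0.15,
                                  sd_ratio_x = 0.5) {
  if (rate >= 0) abort("`rate` must be negative (errors decay).")
  if (asymptote < 0) abort("`asymptote` must be >= 0.")
  if (noise_sd_amp < 0 || noise_sd_asymptote < 0) {
    abort("noise SDs must be >= 0.")
  }
  structure(list(amp = amp, rate = rate, asymptote = asymptote,
                 noise_sd_amp = noise_sd_amp,
                 noise_sd_asymptote = noise_sd_asymptote,
                 bias_amp_y = bias_amp_y, bias_rate_y = bias_rate_y,
                 sd_ratio_x = sd_ratio_x),
            class = "ll_curve")
}

#' Simulate one throwing session
#'
#' Error magnitudes follow the curve in [learning_curve_params()] plus
#' truncated Gaussian jitter; the endpoint direction is drawn from an
#' anisotropic Gaussian whose y-mean carries the decaying overshoot bias,
#' and the endpoint is the direction unit vector scaled by the error, so
#' the resultant error equals the endpoint norm by construction. Choices
#' are left unset; attach them with [simulate_agent_choices()].
#'
#' @param curve [learning_curve_params()].
#' @param cfg [experiment_config()].
#' @param seed Integer seed.
#' @param participant_id Label.
#' @return A list of class `ll_throw_session`: `participant_id`, `errors`,
#'   `final_x`, `final_y`, `choices` (NULL until attached).
#' @export
simulate_throw_session <- function(curve = learning_curve_params(),
                                   cfg = experiment_config(), seed = 1L,
                                   participant_id = "synthetic") {
  withr_seed(seed, {
    k <- seq_len(cfg$n_trials)
    mu <- curve$amp * exp(curve$rate * k) + curve$asymptote
    sigma <- curve$noise_sd_amp * exp(curve$rate * k) + curve$noise_sd_asymptote
    e <- pmax(0, mu + rnorm(cfg$n_trials, 0, sigma))
    # direction: unit vector of an anisotropic draw with decaying +y mean
    dir_y <- curve$bias_amp_y * exp(curve$bias_rate_y * k) +
      rnorm(cfg$n_trials)
    dir_x <- curve$sd_ratio_x * rnorm(cfg$n_trials)
    nrm <- sqrt(dir_x^2 + dir_y^2)
    zero <- nrm == 0
    dir_x[zero] <- 0; dir_y[zero] <- 1; nrm[zero] <- 1
    structure(
      list(participant_id = participant_id,
           errors = e,
           final_x = e * dir_x / nrm,
           final_y = e * dir_y / nrm,
           choices = NULL),
      class = "ll_throw_session"
    )
  })
}

#' @export
print.ll_throw_session <- function(x, ...) {
  cat("<ll_throw_session>", x$participant_id, "|",
      length(x$errors), "trials |",
      if (is.null(x$choices)) "choices unset" else "choices attached", "\n")
  invisible(x)
}

#' @method as_tibble ll_throw_session
#' @export
as_tibble.ll_throw_session <- function(x, ...) {
  tibble(participant_id = x$participant_id,
         trial = seq_along(x$errors),
         final_x = x$final_x, final_y = x$final_y, error = x$errors)
}

#' Agent window parameters
#'
#' A lead-lag agent rolls out the windowed argmax policy on its own error
#' sequence; for robustness the window must span at least 5 trials.
#'
#' @param lead,lag Window lengths (trials); `lead + lag >= 5`.
#' @return A list of class `ll_agent`.
#' @export
agent_params <- function(lead, lag) {
  if (lead < 0 || lag < 0) abort("`lead` and `lag` must be >= 0.")
  if (lead + lag < 5) abort("`lead + lag` must be at least 5.")
  structure(list(lead = as.integer(lead), lag = as.integer(lag)),
            class = "ll_agent")
}

#' Attach lead-lag agent choices to a synthetic session
#'
#' Rolls out the agent's windowed argmax policy ([rollout_policy()]) on the
#' session's errors and stores the resulting choice sequence.
#'
#' @param session An `ll_throw_session`.
#' @param agent [agent_params()].
#' @param targets [target_set()].
#' @param cfg [experiment_config()].
#' @return The session with `choices`, `agent`, and `points` filled in.
#' @export
simulate_agent_choices <- function(session, agent, targets = target_set(),
                                   cfg = experiment_config()) {
  ro <- rollout_policy(session$errors, policy_params(agent$lead, agent$lag),
                       targets, cfg)
  session$choices <- ro$choices
  session$agent <- agent
  session$points <- ro$points
  session
}

#' Simulate a cohort of lead-lag throwing agents
#'
#' Draws per-participant learning curves and agent windows around the
#' population values (windows centred on a 38-trial lead and 46-trial lag)
#' and returns one row per participant with list-columns ready for the
#' fitting and solver pipeline.
#'
#' @param n_participants Cohort size.
#' @param seed Integer seed.
#' @param targets [target_set()].
#' @param cfg [experiment_config()].
#' @param lead_mean,lead_sd,lag_mean,lag_sd Population distribution of the
#'   agents' windows (rounded, clamped at 0, window sum forced >= 5).
#' @param curve Baseline [learning_curve_params()]; amplitude, rate and
#'   asymptote are jittered across participants.
#' @return A tibble: `participant`, `lead`, `lag`, `errors`, `final_x`,
#'   `final_y`, `choices` (list-columns), `points`.
#' @export
simulate_throw_cohort <- function(n_participants = 8, seed = 1L,
                                  targets = target_set(),
                                  cfg = experiment_config(),
                                  lead_mean = 38, lead_sd = 16,
                                  lag_mean = 46, lag_sd = 13,
                                  curve = learning_curve_params()) {
  withr_seed(seed, {
    rows <- purrr::map(seq_len(n_participants), function(i) {
      crv <- learning_curve_params(
        amp = max(20, curve$amp * exp(rnorm(1, 0, 0.25))),
        rate = curve$rate * exp(rnorm(1, 0, 0.3)),
        asymptote = max(5, curve$asymptote + rnorm(1, 0, 8)),
        noise_sd_amp = curve$noise_sd_amp,
        noise_sd_asymptote = curve$noise_sd_asymptote,
        bias_amp_y = curve$bias_amp_y, bias_rate_y = curve$bias_rate_y,
        sd_ratio_x = curve$sd_ratio_x
      )
      lead <- max(0L, round(rnorm(1, lead_mean, lead_sd)))
      lag <- max(0L, round(rnorm(1, lag_mean, lag_sd)))
      if (lead + lag < 5) lead <- 5L - lag
      s <- simulate_throw_session(crv, cfg, seed = sample.int(2^30, 1),
                                  participant_id = paste0("S", i))
      s <- simulate_agent_choices(s, agent_params(lead, lag), targets, cfg)
      tibble(participant = s$participant_id, lead = lead, lag = lag,
             errors = list(s$errors), final_x = list(s$final_x),
             final_y = list(s$final_y), choices = list(s$choices),
             points = s$points)
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate one visuomotor-rotation session
#'
#' Angular errors start at the rotation magnitude (45 degrees) and decay
#' exponentially over the rotated trials (initial learning then harvest),
#' with Gaussian noise; faults are drawn independently at `fault_rate`.
#' Baseline phases carry noise-only errors. The simulated participant's
#' schedule selections anticipate performance: for each horizon, the
#' selected hit value is `60 + 40 * expected hit proportion` over that
#' horizon (computed from the participant's own generating curve), plus
#' selection noise, rounded and clamped to the admissible range.
#'
#' @param decay_rate Exponential decay rate of the angular error per
#'   rotated trial (negative).
#' @param noise_sd Angular noise SD, degrees.
#' @param fault_rate Probability a trial is an RT fault.
#' @param selection_sd SD of the hit-value selection noise, points.
#' @param cfg [exp2_config()].
#' @param seed Integer seed.
#' @param participant_id Label.
#' @return A list of class `ll_reach_session`: `participant_id`, `trials`
#'   (tibble: `trial`, `phase`, `angular_error`, `reaction_time`,
#'   `outcome`), `selected_hit_values` (named by horizon),
#'   `baseline_hit_value`.
#' @export
simulate_reach_session <- function(decay_rate = -0.03, noise_sd = 8,
                                   fault_rate = 0.05, selection_sd = 5,
                                   cfg = exp2_config(), seed = 1L,
                                   participant_id = "synthetic") {
  if (fault_rate < 0 || fault_rate > 1) abort("`fault_rate` must be in [0,1].")
  if (decay_rate >= 0) abort("`decay_rate` must be negative.")
  withr_seed(seed, {
    n_harvest <- max(cfg$horizons)
    phases <- c(rep("baseline_practice", cfg$n_baseline_practice),
                rep("baseline_harvest", cfg$n_baseline_harvest),
                rep("initial_learning", cfg$n_initial_learning),
                rep("harvest", n_harvest))
    n <- length(phases)
    rotated <- phases %in% c("initial_learning", "harvest")
    k_rot <- cumsum(rotated)
    mu <- ifelse(rotated, cfg$rotation * exp(decay_rate * k_rot), 0)
    ang <- mu + rnorm(n, 0, noise_sd)
    fault <- runif(n) < fault_rate
    rt <- ifelse(fault, runif(n, cfg$rt_fault + 1, cfg$rt_fault + 150),
                 runif(n, 150, cfg$rt_fault))
    outcome <- classify_trials(ang, rt, cfg)
    trials <- tibble(trial = seq_len(n), phase = phases,
                     angular_error = ang, reaction_time = rt,
                     outcome = outcome)
    # forward-looking chooser: expected hit proportion over each horizon
    thr <- angular_threshold(cfg)
    hit_prob <- function(mu_h) {
      if (noise_sd == 0) return(as.numeric(abs(mu_h) <= thr))
      stats::pnorm((thr - mu_h) / noise_sd) -
        stats::pnorm((-thr - mu_h) / noise_sd)
    }
    pred_hit <- function(H) {
      kk <- cfg$n_initial_learning + seq_len(H)
      mean(hit_prob(cfg$rotation * exp(decay_rate * kk))) * (1 - fault_rate)
    }
    clamp <- function(v) {
      pmin(cfg$hit_value_range[2], pmax(cfg$hit_value_range[1], round(v)))
    }
    sel <- clamp(60 + 40 * vapply(cfg$horizons, pred_hit, numeric(1)) +
                   rnorm(length(cfg$horizons), 0, selection_sd))
    p_base <- hit_prob(0) * (1 - fault_rate)
    base_sel <- clamp(60 + 40 * p_base + rnorm(1, 0, selection_sd))
    structure(
      list(participant_id = participant_id, trials = trials,
           selected_hit_values = setNames(sel, cfg$horizons),
           baseline_hit_value = base_sel),
      class = "ll_reach_session"
    )
  })
}

#' @export
print.ll_reach_session <- function(x, ...) {
  cat("<ll_reach_session>", x$participant_id, "|", nrow(x$trials),
      "trials | selections:",
      paste(names(x$selected_hit_values), x$selected_hit_values,
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Simulate a visuomotor-rotation cohort
#'
#' Draws per-participant decay rates, noise levels, and fault rates around
#' the defaults of [simulate_reach_session()].
#'
#' @param n_participants Cohort size.
#' @param seed Integer seed.
#' @param cfg [exp2_config()].
#' @return A list of `ll_reach_session` objects.
#' @export
simulate_reach_cohort <- function(n_participants = 17, seed = 1L,
                                  cfg = exp2_config()) {
  withr_seed(seed, {
    purrr::map(seq_len(n_participants), function(i) {
      simulate_reach_session(
        decay_rate = -exp(rnorm(1, log(0.03), 0.5)),
        noise_sd = max(3, rnorm(1, 8, 2)),
        fault_rate = min(0.3, max(0, rnorm(1, 0.05, 0.03))),
        cfg = cfg, seed = sample.int(2^30, 1),
        participant_id = paste0("R", i)
      )
    })
  })
}

#' Perturb a choice sequence with human-like decision noise
#'
#' Deterministic windowed-argmax agents reproduce their own rollouts
#' exactly; human choice sequences do not. This helper emulates that
#' deviation: at each decision, with probability `prob`, the chosen target
#' index is nudged one step up or down, after which the sequence is
#' re-monotonized (cumulative maximum) and clamped to the admissible range,
#' so the result is always a valid never-larger sequence.
#'
#' @param choices A monotone choice sequence.
#' @param prob Per-decision perturbation probability.
#' @param seed Integer seed.
#' @param n_targets Number of targets.
#' @return A perturbed, still-valid choice sequence.
#' @export
perturb_choices <- function(choices, prob = 0.3, seed = 1L, n_targets = 6L) {
  if (prob < 0 || prob > 1) abort("`prob` must be in [0, 1].")
  withr_seed(seed, {
    n <- length(choices)
    delta <- sample(c(-1L, 1L), n, replace = TRUE) *
      (runif(n) < prob)
    out <- pmin(n_targets, pmax(1L, as.integer(choices) + delta))
    as.integer(cummax(out))
  })
}
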