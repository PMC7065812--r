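# Shared fixtures: small configurations and deterministic toy sessions.

toy_targets <- function(...) target_set(...)

# two-block toy: block 1 forced on target 1, one decision
toy_cfg2 <- function() experiment_config(n_trials = 10, block_size = 5)

toy_errors2 <- function() c(300, 120, 60, 45, 30, rep(30, 5))

# independent oracle for the windowed value: literal sum over the window
oracle_window_value <- function(i, j, lead, lag, errors, targets,
                                cfg = experiment_config()) {
  lo <- max(1, cfg$block_size * j - lag)
  hi <- min(cfg$block_size * j + lead, cfg$n_trials)
  total <- 0
  for (k in lo:hi) {
    total <- total +
      targets$values[i] * as.integer(targets$radii[i] +
                                       targets$hit_margin - errors[k] >= 0)
  }
  total
}

# independent oracle for session scoring: per-trial loop
oracle_score <- function(errors, choices, targets, cfg) {
  block_targets <- c(1L, choices)
  total <- 0
  for (k in seq_along(errors)) {
    b <- (k - 1) %/% cfg$block_size + 1
    i <- block_targets[b]
    hit <- as.integer(targets$radii[i] + targets$hit_margin - errors[k] >= 0)
    total <- total + targets$values[i] * hit
  }
  total
}

# enumerate all non-decreasing sequences of length d over t symbols
enumerate_scenarios <- function(d, t) {
  if (d == 1) return(lapply(seq_len(t), function(i) i))
  out <- list()
  for (rest in enumerate_scenarios(d - 1, t)) {
    for (q in seq_len(t)) {
      if (q >= rest[[length(rest)]]) out[[length(out) + 1]] <- c(rest, q)
    }
  }
  out
}

# random short session for solver cross-checks
random_session_errors <- function(n_trials, seed) {
  set.seed(seed)
  pmax(0, 250 * exp(-0.03 * seq_len(n_trials)) +
         rnorm(n_trials, 0, 40))
}

small_cohort <- function(n = 3, seed = 42) {
  simulate_throw_cohort(n, seed = seed)
}
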