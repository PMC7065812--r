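test_that("scenario counting matches enumeration and the stars-and-bars form", {
  expect_equal(count_scenarios(2, 2), 3)
  expect_equal(count_scenarios(1, 4), 4)
  expect_equal(count_scenarios(39, 6), 1086008)
  for (d in 1:5) {
    for (t in 1:4) {
      expect_equal(count_scenarios(d, t), length(enumerate_scenarios(d, t)))
      expect_equal(count_scenarios(d, t), choose(d + t - 1, t - 1))
    }
  }
})

test_that("dynamic program solves the two-block toy exactly", {
  cfg <- toy_cfg2()
  ts <- toy_targets()
  sol <- global_optimal_dp(toy_errors2(), ts, cfg)
  # block 1 forced: errors (300,120,60,45,30) on 208 mm -> 4 hits x 1 point;
  # block 2 all 30 mm -> target 6 gives 5 x 6 = 30
  expect_equal(sol$points, 34)
  expect_equal(sol$choices, 6L)
  all_out <- rep(250, 10)
  sol0 <- global_optimal_dp(all_out, ts, cfg)
  expect_equal(sol0$points, 0)
  expect_equal(sol0$choices, 1L) # lexicographic tie-break
})

test_that("dynamic program agrees with brute force on random sessions", {
  ts <- toy_targets()
  cfg <- experiment_config(n_trials = 25, block_size = 5) # 4 decisions
  for (seed in 1:20) {
    e <- random_session_errors(25, seed)
    dp <- global_optimal_dp(e, ts, cfg)
    bf <- global_optimal_bruteforce(e, ts, cfg)
    expect_equal(dp$points, bf$points)
    expect_equal(dp$choices, bf$choices)
  }
})

test_that("brute force enumerates exactly the scenario count", {
  ts <- toy_targets()
  cfg <- experiment_config(n_trials = 20, block_size = 5) # 3 decisions
  bf <- global_optimal_bruteforce(random_session_errors(20, 3), ts, cfg)
  expect_equal(bf$n_visited, count_scenarios(3, 6))
  expect_equal(bf$n_visited, choose(8, 5))
})

test_that("the scenario distribution matches enumeration and ranks correctly", {
  ts <- toy_targets()
  cfg <- experiment_config(n_trials = 15, block_size = 5) # 2 decisions
  e <- random_session_errors(15, 8)
  dist <- scenario_distribution(e, ts, cfg)
  scen <- enumerate_scenarios(2, 6)
  totals <- vapply(scen, function(ch) score_points(e, ch, ts, cfg), numeric(1))
  expect_equal(dist$n_total, length(scen))
  expect_equal(dist$mean, mean(totals))
  expect_equal(dist$sd, sd(totals) * sqrt((length(totals) - 1) / length(totals)))
  expect_equal(dist$max, max(totals))
  expect_equal(dist$min, min(totals))
  # the optimum ranks first at the 100th percentile
  dp <- global_optimal_dp(e, ts, cfg)
  r <- scenario_rank(dist, dp$points)
  expect_equal(r$rank, 1)
  expect_equal(r$percentile, 100)
  # hand percentile of an arbitrary scenario
  some <- totals[3]
  r2 <- scenario_rank(dist, some)
  expect_equal(r2$percentile, 100 * mean(totals <= some))
  expect_equal(r2$zscore, (some - dist$mean) / dist$sd)
})

test_that("the distribution's extreme equals the DP optimum on the full task", {
  ts <- toy_targets()
  cfg <- experiment_config()
  e <- random_session_errors(200, 17)
  dist <- scenario_distribution(e, ts, cfg)
  expect_equal(dist$n_total, count_scenarios(39, 6))
  expect_equal(dist$max, global_optimal_dp(e, ts, cfg)$points)
})

test_that("the global optimum dominates every rollout policy and participant", {
  ts <- toy_targets()
  cfg <- experiment_config()
  set.seed(4)
  for (rep in 1:3) {
    e <- random_session_errors(200, 100 + rep)
    opt <- global_optimal_dp(e, ts, cfg)$points
    for (k in 1:5) {
      pol <- policy_params(sample(0:80, 1), sample(0:80, 1))
      expect_lte(rollout_policy(e, pol, ts, cfg)$points, opt)
    }
    random_choices <- sort(sample(1:6, 39, replace = TRUE))
    expect_lte(score_points(e, random_choices, ts, cfg), opt)
  }
})

test_that("local-optimal search equals exhaustive evaluation on a small grid", {
  ts <- toy_targets()
  cfg <- experiment_config()
  e <- random_session_errors(200, 55)
  loc <- local_optimal_search(e, ts, cfg, lead_range = 0:2, lag_range = 0:2,
                              keep_grid = TRUE)
  direct <- vapply(seq_len(nrow(loc$grid)), function(i) {
    rollout_policy(e, policy_params(loc$grid$lead[i], loc$grid$lag[i]),
                   ts, cfg)$points
  }, numeric(1))
  expect_equal(loc$grid$points, direct)
  expect_equal(loc$points, max(direct))
  # all-hit session: every policy identical, tie-break returns (0, 0)
  loc0 <- local_optimal_search(rep(0, 200), ts, cfg,
                               lead_range = 0:3, lag_range = 0:3)
  expect_equal(c(loc0$policy$lead, loc0$policy$lag), c(0L, 0L))
  expect_error(local_optimal_search(e, ts, cfg, lead_range = integer(0)),
               "non-empty")
})

test_that("minimax target design spreads occupancy and beats random sets", {
  cfg <- experiment_config(n_trials = 60, block_size = 5)
  # error decays through six well-separated plateaus
  plateaus <- rep(c(180, 90, 55, 42, 34, 28), each = 10)
  des <- design_targets_minimax(list(plateaus), n_targets = 6,
                                hit_rate_floor = 0.5, cfg = cfg,
                                radius_grid = seq(10, 250, by = 10),
                                n_random = 30, seed = 2)
  expect_true(des$feasible)
  expect_equal(sum(des$occupancy$trials), 60)
  # near-equal occupancy is achievable: 10 trials per target
  expect_lte(des$objective, 15)
  # dominance over random candidate sets
  set.seed(9)
  for (k in 1:20) {
    radii <- sort(sample(seq(10, 250, by = 10), 6), decreasing = TRUE)
    ts <- target_set(radii = radii)
    sol <- global_optimal_dp(plateaus, ts, cfg)
    occ <- tabulate(sol$block_targets, 6) * cfg$block_size
    hm <- hit_matrix(plateaus, ts)
    hits <- sum(hm[cbind(seq_along(plateaus),
                         rep(sol$block_targets, each = cfg$block_size))])
    if (hits / 60 > 0.5) expect_lte(des$objective, max(occ))
  }
})

test_that("single-target design returns the smallest radius above the floor", {
  cfg <- experiment_config(n_trials = 10, block_size = 5)
  e <- rep(c(40, 60), 5)
  des <- design_targets_minimax(list(e), n_targets = 1, hit_rate_floor = 0.5,
                                cfg = cfg, radius_grid = c(30, 45, 65, 100),
                                n_random = 4, seed = 1)
  expect_true(des$feasible)
  expect_equal(des$radii, 65) # 45 hits only half; floor requires > 0.5
})
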