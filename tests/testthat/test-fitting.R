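test_that("fitting recovers a grid-representable generating policy with zero SSE", {
  cfg <- experiment_config()
  ts <- toy_targets()
  s <- simulate_throw_session(seed = 7)
  s <- simulate_agent_choices(s, agent_params(18, 14), ts, cfg)
  fit <- fit_policy(s$choices, s$errors, ts, cfg,
                    lead_range = 0:30, lag_range = 0:30)
  expect_equal(fit$sse, 0)
  expect_equal(fit$mad, 0)
  # the recovered policy's rollout must equal the generating rollout
  ro <- rollout_policy(s$errors, fit$policy, ts, cfg)
  expect_equal(ro$choices, s$choices)
})

test_that("off-by-one-everywhere predictions give MAD exactly 1", {
  cfg <- experiment_config()
  ts <- toy_targets()
  s <- simulate_throw_session(seed = 3)
  # clamp errors above the smallest radius so the agent never reaches
  # target 6 and an everywhere-one-larger observer stays admissible
  s$errors <- pmax(s$errors, 35)
  s$final_x <- NULL
  s <- simulate_agent_choices(s, agent_params(10, 10), ts, cfg)
  pred <- s$choices
  expect_lte(max(pred), 5L)
  observed <- pred + 1L
  # at the generating window the model is off by one target at every
  # decision: MAD 1, SSE 39
  expect_equal(mean(abs(pred - observed)), 1)
  fit <- fit_policy(observed, s$errors, ts, cfg,
                    lead_range = 0:20, lag_range = 0:20)
  expect_lte(fit$mad, 1) # the best grid point can only do better
  expect_lte(fit$sse, 39)
})

test_that("the lead-lag SSE is nested below both single-window models", {
  cfg <- experiment_config()
  ts <- toy_targets()
  coh <- small_cohort(4, seed = 12)
  for (i in seq_len(nrow(coh))) {
    # perturb observed choices so fits are not trivially zero
    obs <- coh$choices[[i]]
    obs[c(5, 20)] <- pmin(6L, obs[c(5, 20)] + 1L)
    obs <- cummax(obs)
    fits <- lapply(c("leadlag", "lead", "lag"), function(m) {
      fit_policy(obs, coh$errors[[i]], ts, cfg, mode = m,
                 lead_range = 0:60, lag_range = 0:60)
    })
    expect_lte(fits[[1]]$sse, min(fits[[2]]$sse, fits[[3]]$sse))
    # SSE and MAD agree on zero
    expect_equal(fits[[1]]$sse == 0, fits[[1]]$mad == 0)
  }
})

test_that("one-parameter modes pin the other window at zero", {
  cfg <- experiment_config()
  ts <- toy_targets()
  s <- simulate_throw_session(seed = 5)
  s <- simulate_agent_choices(s, agent_params(12, 3), ts, cfg)
  f_lead <- fit_policy(s$choices, s$errors, ts, cfg, mode = "lead",
                       lead_range = 0:40)
  f_lag <- fit_policy(s$choices, s$errors, ts, cfg, mode = "lag",
                      lag_range = 0:40)
  expect_equal(f_lead$policy$lag, 0L)
  expect_equal(f_lag$policy$lead, 0L)
  expect_gte(f_lead$policy$lead, 5L) # lead + lag >= 5 with lag 0
})

test_that("the nested F statistic matches its formula and the reported values", {
  # zero improvement: F = 0, p = 1
  t0 <- nested_f_test(100, 100, params_reduced = 8, params_full = 16,
                      n_obs = 312)
  expect_equal(t0$f_stat, 0)
  expect_equal(t0$p_value, 1)
  # pooled residuals of the one- vs two-window models, 8 participants:
  # the published statistics round the residual sums, so allow 0.5
  t_lead <- nested_f_test(524, 347, params_reduced = 8, params_full = 16,
                          n_obs = 312)
  expect_equal(t_lead$df_num, 8)
  expect_equal(t_lead$df_den, 296)
  expect_equal(t_lead$f_stat, 18.84, tolerance = 0.5 / 18.84)
  t_lag <- nested_f_test(999, 347, params_reduced = 8, params_full = 16,
                         n_obs = 312)
  expect_equal(t_lag$f_stat, 69.46, tolerance = 0.5 / 69.46)
  expect_error(nested_f_test(10, 5, params_reduced = 2, params_full = 2,
                             n_obs = 10), "more parameters")
  expect_error(nested_f_test(10, 5, params_reduced = 1, params_full = 12,
                             n_obs = 10), "exceed")
})

test_that("with one numerator df the F statistic is the squared t statistic", {
  set.seed(14)
  x <- rnorm(30)
  y <- 2 + 0.7 * x + rnorm(30)
  full <- lm(y ~ x)
  reduced <- lm(y ~ 1)
  ft <- nested_f_test(sum(resid(reduced)^2), sum(resid(full)^2),
                      params_reduced = 1, params_full = 2, n_obs = 30)
  tstat <- summary(full)$coefficients["x", "t value"]
  expect_equal(ft$f_stat, tstat^2, tolerance = 1e-10)
  expect_equal(ft$df_num, 1)
})

test_that("pooled fits sum per-participant residuals and nest across modes", {
  cfg <- experiment_config()
  ts <- toy_targets()
  coh <- small_cohort(3, seed = 20)
  pooled <- lapply(c("leadlag", "lead", "lag"), function(m) {
    pooled_fit(coh, ts, cfg, mode = m, lead_range = 0:60, lag_range = 0:60)
  })
  expect_equal(pooled[[1]]$sse,
               sum(vapply(pooled[[1]]$fits, function(f) f$sse, numeric(1))))
  expect_equal(pooled[[1]]$n_obs, 3 * 39)
  expect_equal(pooled[[1]]$n_params, 6)
  expect_equal(pooled[[2]]$n_params, 3)
  expect_lte(pooled[[1]]$sse, pooled[[2]]$sse)
  expect_lte(pooled[[1]]$sse, pooled[[3]]$sse)
  # synthetic agents are grid-representable: lead-lag recovers them exactly
  expect_equal(pooled[[1]]$sse, 0)
  # single participant pools to the individual fit
  solo <- pooled_fit(coh[1, ], ts, cfg, mode = "lead", lead_range = 0:60)
  expect_equal(solo$sse, solo$fits[[1]]$sse)
})

test_that("the sensitivity surface peaks at zero offset and matches recomputation", {
  cfg <- experiment_config()
  ts <- toy_targets()
  s <- simulate_throw_session(seed = 9)
  s <- simulate_agent_choices(s, agent_params(20, 15), ts, cfg)
  fit <- fit_policy(s$choices, s$errors, ts, cfg,
                    lead_range = 0:40, lag_range = 0:40)
  surf <- sensitivity_surface(list(fit), list(s), ts, cfg, offsets = 0:3,
                              fold = FALSE)
  at0 <- surf$r2[surf$lead_offset == 0 & surf$lag_offset == 0]
  expect_equal(at0, 1) # perfect fit at the optimum
  expect_true(all(surf$r2 <= at0 + 1e-12))
  # direct recomputation at one offset
  obs <- s$choices
  sst <- sum((obs - mean(obs))^2)
  pred <- rollout_policy(s$errors,
                         policy_params(fit$policy$lead + 2,
                                       fit$policy$lag - 1), ts, cfg)$choices
  want <- 1 - sum((pred - obs)^2) / sst
  got <- surf$r2[surf$lead_offset == 2 & surf$lag_offset == -1]
  expect_equal(got, want)
  # folded surface averages the +/- displacements
  surf_f <- sensitivity_surface(list(fit), list(s), ts, cfg, offsets = 0:2)
  expect_true(all(surf_f$lead_offset >= 0))
})
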