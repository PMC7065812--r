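test_that("the angular hit threshold follows the small-angle geometry", {
  expect_equal(round(angular_threshold(), 2), 5.73)
  expect_equal(angular_threshold(exp2_config(target_radius = 0)), 0)
  # doubling the amplitude halves the threshold
  expect_equal(angular_threshold(exp2_config(amplitude = 200)),
               angular_threshold() / 2)
})

test_that("trial classification applies the fault and hit rules in order", {
  cfg <- exp2_config()
  thr <- angular_threshold(cfg)
  expect_equal(classify_trials(0, 360, cfg), "fault") # fault even with 0 error
  expect_equal(classify_trials(thr, 200, cfg), "hit") # boundary inclusive
  expect_equal(classify_trials(10, 200, cfg), "miss")
  expect_equal(classify_trials(-thr / 2, 200, cfg), "hit") # absolute error
  expect_equal(classify_trials(c(0, 10, 0), c(200, 200, 351), cfg),
               c("hit", "miss", "fault"))
})

test_that("reward lines carry the h/m/f proportions and linear form", {
  # h = m = 0.5: flat line at 50
  line <- reward_line(rep(c("hit", "miss"), 5))
  expect_equal(line$slope, 0)
  expect_equal(expected_reward(line, c(60, 80, 100)), rep(50, 3))
  # h = 0.9, m = 0.1
  line2 <- reward_line(c(rep("hit", 9), "miss"))
  expect_equal(expected_reward(line2, 100), 90)
  expect_equal(expected_reward(line2, 60), 58)
  expect_equal(line2$slope, 0.8)
  # proportions always sum to one
  line3 <- reward_line(c("hit", "miss", "fault", "hit"))
  expect_equal(line3$hit_prop + line3$miss_prop + line3$fault_prop, 1)
  # horizon truncation and errors
  expect_equal(reward_line(c(rep("hit", 3), rep("miss", 7)), horizon = 3)$hit_prop, 1)
  expect_error(reward_line(rep("hit", 5), horizon = 10), "exceeds")
  expect_error(reward_line(character(0)), "non-empty")
})

test_that("the optimal hit value sits at the range end given the slope sign", {
  up <- reward_line(c(rep("hit", 9), "miss"))
  down <- reward_line(c("hit", rep("miss", 9)))
  flat <- reward_line(rep(c("hit", "miss"), 5))
  expect_equal(optimal_hit_value(up), 100)
  expect_equal(optimal_hit_value(down), 60)
  expect_true(is.na(optimal_hit_value(flat))) # indifferent
})

test_that("reward extremes bound the realized reward", {
  line <- reward_line(c(rep("hit", 9), "miss"))
  ext <- reward_extremes(line, 80)
  expect_equal(ext$max_reward, 90)
  expect_equal(ext$min_reward, 58)
  expect_gte(ext$actual_reward, ext$min_reward)
  expect_lte(ext$actual_reward, ext$max_reward)
  flat <- reward_line(rep(c("hit", "miss"), 5))
  ext0 <- reward_extremes(flat, 70)
  expect_equal(ext0$min_reward, ext0$max_reward)
  expect_equal(ext0$min_reward, ext0$actual_reward)
  expect_error(reward_extremes(line, 50), "admissible")
})

test_that("horizon adjustment removes per-horizon means and matches hand work", {
  # single horizon: the adjustment is the identity
  pts1 <- tibble::tibble(horizon = 24, slope = c(-0.1, 0, 0.2),
                         hit_value = c(60, 70, 90))
  out1 <- adjusted_correlation(pts1)
  expect_equal(out1$r, cor(pts1$slope, pts1$hit_value))
  # two horizons x three participants, hand-computed
  pts <- tibble::tibble(
    horizon = rep(c(24, 216), each = 3),
    slope = c(-0.2, -0.1, 0.1, 0.1, 0.2, 0.4),
    hit_value = c(62, 66, 73, 75, 80, 92)
  )
  adj_s <- with(pts, slope - ave(slope, horizon) + mean(slope))
  adj_v <- with(pts, hit_value - ave(hit_value, horizon) + mean(hit_value))
  out <- adjusted_correlation(pts)
  expect_equal(out$r, cor(adj_s, adj_v))
  # invariance to a constant shift within one horizon
  pts_shift <- pts
  pts_shift$hit_value[pts_shift$horizon == 216] <-
    pts_shift$hit_value[pts_shift$horizon == 216] + 15
  expect_equal(adjusted_correlation(pts_shift)$r, out$r)
  # exact linear relation survives adjustment with r = 1
  lin <- tibble::tibble(horizon = rep(c(1, 2), each = 3),
                        slope = c(1, 2, 3, 4, 5, 6))
  lin$hit_value <- 10 + 5 * lin$slope
  expect_equal(adjusted_correlation(lin)$r, 1)
})

test_that("fold-wise CV sums of squares match per-fold lm fits", {
  set.seed(8)
  x <- rnorm(20)
  y <- 1 + 2 * x + rnorm(20)
  fold_id <- sample(rep(1:4, 5))
  res <- leadlag:::cv_fold_sse(x, cbind(y), fold_id)
  sse_lin <- 0; sse_mean <- 0
  for (k in 1:4) {
    train <- fold_id != k
    fit <- lm(y ~ x, subset = train)
    pred <- coef(fit)[1] + coef(fit)[2] * x[!train]
    sse_lin <- sse_lin + sum((y[!train] - pred)^2)
    sse_mean <- sse_mean + sum((y[!train] - mean(y[train]))^2)
  }
  expect_equal(res$lin[1], sse_lin)
  expect_equal(res$mean[1], sse_mean)
})

test_that("the predictive correlation is near one for clean linear data and reproducible", {
  pts <- tibble::tibble(slope = seq(-1, 1, length.out = 30))
  pts$hit_value <- 75 + 10 * pts$slope
  out <- cv_predictive_r(pts, reps = 20, perms = 99, seed = 4)
  expect_gt(out$r, 0.97)
  expect_lt(out$p_value, 0.05)
  out2 <- cv_predictive_r(pts, reps = 20, perms = 99, seed = 4)
  expect_identical(out, out2)
  # negative association carries a negative sign
  pts$hit_value <- 75 - 10 * pts$slope
  expect_lt(cv_predictive_r(pts, reps = 20, perms = 0, seed = 4)$r, -0.97)
})

test_that("repeated-measures ANOVA matches aov and hand sums of squares", {
  set.seed(10)
  d <- tidyr::expand_grid(participant = factor(1:6), condition = factor(1:3))
  d$value <- rnorm(nrow(d)) + as.numeric(d$condition) * 0.5
  out <- rm_anova(d)
  ref <- summary(aov(value ~ condition + Error(participant), data = d))
  ref_f <- ref[["Error: Within"]][[1]]["condition", "F value"]
  expect_equal(out$f_stat, ref_f, tolerance = 1e-10)
  expect_equal(out$df_num, 2)
  expect_equal(out$df_den, 10)
  # identical condition means within participant: F = 0
  d0 <- tidyr::expand_grid(participant = factor(1:4), condition = factor(1:3))
  d0$value <- as.numeric(d0$participant)
  expect_equal(rm_anova(d0)$f_stat, 0)
  # df structure at the study's size
  d17 <- tidyr::expand_grid(participant = factor(1:17), condition = factor(1:3))
  d17$value <- rnorm(nrow(d17))
  expect_equal(rm_anova(d17)$df_den, 32)
  expect_error(rm_anova(d17[-1, ]), "complete")
})

test_that("Holm correction reproduces the hand step-down", {
  out <- holm_bonferroni(c(0.01, 0.02, 0.04))
  expect_equal(out$p_adjusted, c(0.03, 0.04, 0.04))
  expect_true(all(out$reject))
  expect_equal(holm_bonferroni(0.03)$p_adjusted, 0.03)
  expect_false(any(holm_bonferroni(rep(1, 4))$reject))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hit proportions are computed per horizon with optional fault exclusion", {
  cfg <- exp2_config()
  outcomes <- c(rep("miss", 24), rep("hit", 126), rep(c("hit", "fault"), 33))
  hp <- horizon_hit_proportions(outcomes, cfg)
  expect_equal(hp$horizon, c(24L, 150L, 216L))
  expect_equal(hp$hit_prop[1], 0)
  expect_equal(hp$hit_prop[2], 126 / 150)
  expect_equal(hp$hit_prop[3], (126 + 33) / 216)
  hp_x <- horizon_hit_proportions(outcomes, cfg, include_faults = FALSE)
  expect_equal(hp_x$hit_prop[3], (126 + 33) / (216 - 33))
})
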