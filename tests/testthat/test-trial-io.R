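test_that("throw sessions round-trip through the CSV dialect unchanged", {
  dir <- withr::local_tempdir()
  coh <- small_cohort(2, seed = 6)
  tp <- file.path(dir, "trials.csv")
  cp <- file.path(dir, "choices.csv")
  write_throw_sessions(coh, tp, cp)
  back <- read_throw_sessions(tp, cp)
  orig <- leadlag:::as_throw_session_list(coh)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(back[[i]]$participant_id, orig[[i]]$participant_id)
    expect_equal(back[[i]]$errors, orig[[i]]$errors)
    expect_equal(back[[i]]$final_x, orig[[i]]$final_x)
    expect_equal(back[[i]]$final_y, orig[[i]]$final_y)
    expect_identical(back[[i]]$choices, as.integer(orig[[i]]$choices))
  }
})

test_that("reach sessions round-trip through the CSV dialect unchanged", {
  dir <- withr::local_tempdir()
  sessions <- simulate_reach_cohort(2, seed = 8)
  tp <- file.path(dir, "reach_trials.csv")
  sp <- file.path(dir, "selections.csv")
  write_reach_sessions(sessions, tp, sp)
  back <- read_reach_sessions(tp, sp)
  for (i in 1:2) {
    expect_equal(back[[i]]$participant_id, sessions[[i]]$participant_id)
    expect_equal(back[[i]]$trials$angular_error,
                 sessions[[i]]$trials$angular_error)
    expect_equal(back[[i]]$trials$outcome, sessions[[i]]$trials$outcome)
    expect_equal(back[[i]]$trials$phase, sessions[[i]]$trials$phase)
    expect_equal(unname(back[[i]]$selected_hit_values),
                 unname(as.integer(sessions[[i]]$selected_hit_values)))
    expect_equal(back[[i]]$baseline_hit_value,
                 as.integer(sessions[[i]]$baseline_hit_value))
  }
})

test_that("malformed headers are rejected with the expected column list", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  readr::write_csv(tibble::tibble(x = 1, y = 2), bad)
  good_choices <- file.path(dir, "choices.csv")
  readr::write_csv(tibble::tibble(participant_id = "a", decision = 1,
                                  target_index = 1), good_choices)
  expect_error(read_throw_sessions(bad, good_choices), "expected columns")
})

test_that("session validation reports each violated invariant", {
  cfg <- experiment_config()
  coh <- small_cohort(1, seed = 13)
  s <- leadlag:::as_throw_session_list(coh)[[1]]
  expect_equal(nrow(validate_throw_session(s, cfg)), 0)
  # trial-count violation
  s_short <- s
  s_short$errors <- s_short$errors[1:199]
  s_short$final_x <- NULL
  rep1 <- validate_throw_session(s_short, cfg)
  expect_true(any(grepl("199", rep1$message)))
  # monotonicity violation (3 then 2)
  s_dec <- s
  s_dec$choices <- c(3L, 2L, rep(2L, 37))
  rep2 <- validate_throw_session(s_dec, cfg)
  expect_true(any(grepl("decrease", rep2$message)))
  # non-decreasing choices pass
  s_ok <- s
  s_ok$choices <- cummax(s_ok$choices)
  expect_equal(nrow(validate_throw_session(s_ok, cfg)), 0)
  # coordinate inconsistency
  s_bad <- s
  s_bad$final_x <- s_bad$final_x + 5
  rep3 <- validate_throw_session(s_bad, cfg)
  expect_true(any(grepl("resultant", rep3$message)))
})

test_that("the Level-5 MAT reader agrees with files written by an external writer", {
  dir <- withr::local_tempdir()
  mat <- file.path(dir, "ref.mat")
  script <- file.path(dir, "make.py")
  writeLines(c(
    "import scipy.io, numpy as np",
    "rng = np.random.default_rng(5)",
    "scipy.io.savemat(r'PATH', {",
    "  'mat': np.arange(12.0).reshape(3, 4, order='F'),",
    "  'vec': np.array([1.5, -2.5, 3.5]),",
    "  'ints': np.array([[1, 2, 3]], dtype=np.int32),",
    "  'txt': 'session one',",
    "  'st': {'a': np.array([7.0]), 'b': 'xy'},",
    "  'cl': np.array([np.array([1.0, 2.0]), 'z'], dtype=object),",
    "}, do_compression=True)"
  ) |> gsub(pattern = "PATH", replacement = mat, fixed = TRUE), script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(mat))
  got <- read_mat(mat)
  expect_equal(got$mat, matrix(0:11, 3, 4))
  expect_equal(got$vec, c(1.5, -2.5, 3.5))
  expect_equal(got$ints, c(1L, 2L, 3L))
  expect_equal(got$txt, "session one")
  expect_equal(got$st$a, 7)
  expect_equal(got$st$b, "xy")
  expect_equal(got$cl[[1]], c(1, 2))
  expect_equal(got$cl[[2]], "z")
  expect_error(read_mat(file.path(dir, "absent.mat")), "not found")
  # corrupt file: too short / wrong magic
  junk <- file.path(dir, "junk.mat")
  writeBin(as.raw(1:64), junk)
  expect_error(read_mat(junk), "too short")
  junk2 <- file.path(dir, "junk2.mat")
  writeBin(as.raw(rep(32, 200)), junk2)
  expect_error(read_mat(junk2), "endian")
})

test_that("a study container in the documented layout loads into validated sessions", {
  dir <- withr::local_tempdir()
  mat <- file.path(dir, "study.mat")
  coh <- small_cohort(2, seed = 44)
  reach <- simulate_reach_cohort(2, seed = 45)
  # stage the arrays as CSV for the writer script
  err <- do.call(cbind, coh$errors)
  fx <- do.call(cbind, coh$final_x)
  fy <- do.call(cbind, coh$final_y)
  ch <- do.call(cbind, coh$choices)
  ang <- vapply(reach, function(s) s$trials$angular_error, numeric(378))
  rt <- vapply(reach, function(s) s$trials$reaction_time, numeric(378))
  sel <- vapply(reach, function(s) unname(s$selected_hit_values), numeric(3))
  base <- vapply(reach, function(s) s$baseline_hit_value, numeric(1))
  stage <- function(x, name) {
    utils::write.table(x, file.path(dir, paste0(name, ".csv")), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  stage(err, "err"); stage(fx, "fx"); stage(fy, "fy"); stage(ch, "ch")
  stage(ang, "ang"); stage(rt, "rt"); stage(sel, "sel")
  stage(rbind(base), "base")
  script <- file.path(dir, "make_study.py")
  writeLines(c(
    "import scipy.io, numpy as np, os",
    sprintf("d = r'%s'", dir),
    "ld = lambda n: np.loadtxt(os.path.join(d, n + '.csv'), delimiter=',', ndmin=2)",
    "scipy.io.savemat(os.path.join(d, 'study.mat'), {",
    "  'exp1': {'errors': ld('err'), 'final_x': ld('fx'),",
    "           'final_y': ld('fy'), 'choices': ld('ch')},",
    "  'exp2': {'angular_error': ld('ang'), 'reaction_time': ld('rt'),",
    "           'selected_hit_values': ld('sel'),",
    "           'baseline_hit_value': ld('base')},",
    "}, do_compression=True)"
  ), script)
  system2("python", script, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(mat))
  study <- read_study_data(mat)
  expect_length(study$throw_sessions, 2)
  expect_length(study$reach_sessions, 2)
  expect_equal(nrow(study$validation), 0)
  expect_equal(study$throw_sessions[[1]]$errors, coh$errors[[1]])
  expect_identical(study$throw_sessions[[2]]$choices,
                   as.integer(coh$choices[[2]]))
  expect_equal(study$reach_sessions[[1]]$trials$angular_error,
               reach[[1]]$trials$angular_error)
  # outcomes are reconstructed from error and RT on the way in
  expect_equal(study$reach_sessions[[1]]$trials$outcome,
               reach[[1]]$trials$outcome)
  # schema mismatch names the offending field
  script2 <- file.path(dir, "make_bad.py")
  writeLines(c(
    "import scipy.io, numpy as np, os",
    sprintf("d = r'%s'", dir),
    "scipy.io.savemat(os.path.join(d, 'bad.mat'),",
    "  {'exp1': {'errors': np.zeros((200, 1))}})"
  ), script2)
  system2("python", script2, stdout = TRUE, stderr = TRUE)
  expect_error(read_study_data(file.path(dir, "bad.mat")), "final_x")
})
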