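# Trial assembly and session running: structure, counterbalancing,
# blinding, and reproducibility.

std_exp1 <- build_uniform(0.4, 23.6, 1)
cmp_exp1 <- build_symmetric_notched(0.4, 23.6, 19, 1)

test_that("oddity trials are well-formed and share the trial direction", {
  tr <- make_oddity_trial(std_exp1, cmp_exp1, seed = 4)
  expect_s3_class(tr, "rdk_trial")
  expect_length(tr$intervals, 3)
  expect_true(tr$odd_index %in% 1:3)
  expect_gte(tr$trial_direction, 0)
  expect_lt(tr$trial_direction, 360)
  dirs <- unlist(lapply(tr$intervals, function(s) unique(as.vector(s$directions))))
  expect_equal(unique(dirs), tr$trial_direction)   # all intervals share it
  # the two standard intervals are different samples
  stds <- setdiff(1:3, tr$odd_index)
  expect_false(identical(tr$intervals[[stds[1]]]$speeds,
                         tr$intervals[[stds[2]]]$speeds))
  # comparison = standard (zero notch) is well-formed
  tr0 <- make_oddity_trial(std_exp1, build_symmetric_notched(0.4, 23.6, 0, 1),
                           seed = 1)
  expect_length(tr0$intervals, 3)
  expect_error(make_oddity_trial(std_exp1, build_uniform(1.2, 8, 0.4)),
               "not statistics-matched")
})

test_that("direction trials fix the trial speed across intervals", {
  std <- build_direction_gapped(58, 30, 0, 1)
  cmp <- build_direction_gapped(58, 30, 26, 1)
  expect_error(make_oddity_trial(std, cmp), "trial_speed")
  tr <- make_oddity_trial(std, cmp, trial_speed = 13, seed = 2)
  expect_equal(unique(as.vector(tr$intervals[[1]]$speeds)), 13)
  expect_equal(unique(as.vector(tr$intervals[[3]]$speeds)), 13)
})

test_that("odd position is counterbalanced over many trials", {
  set.seed(60)
  pos <- replicate(3000, make_oddity_trial(std_exp1, cmp_exp1,
                                           detail = "none")$odd_index)
  freq <- tabulate(pos, 3) / 3000
  expect_true(all(abs(freq - 1/3) < 3 * sqrt((1/3) * (2/3) / 3000)))
})

test_that("dmax trials displace every dot identically, left or right at random", {
  tr <- make_dmax_trial(100, detail = "speeds", seed = 6)
  expect_equal(tr$dmax_displacement_deg, 5 / 3, tolerance = 1e-12)
  expect_true(tr$dmax_direction %in% c("left", "right"))
  expect_length(unique(as.vector(tr$intervals[[1]]$speeds)), 1)
  expect_equal(unique(as.vector(tr$intervals[[1]]$directions)),
               if (tr$dmax_direction == "right") 0 else 180)
  set.seed(8)
  sides <- replicate(2000, make_dmax_trial(27)$dmax_direction)
  expect_lt(abs(mean(sides == "left") - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("observer views never contain the ground truth", {
  tr <- make_oddity_trial(std_exp1, cmp_exp1, seed = 3)
  v <- observer_view(tr)
  expect_null(v$odd_index)
  expect_false(is.null(tr$odd_index))
  td <- make_dmax_trial(81, seed = 3)
  expect_null(observer_view(td)$dmax_direction)
})

test_that("sessions are reproducible and score the omniscient bound at 1", {
  conds <- list(list(label = "notch_19", param = 19,
                     standard = std_exp1, comparison = cmp_exp1))
  log1 <- run_session(conds, observer_guessing(), 100, seed = 12)
  log2 <- run_session(conds, observer_guessing(), 100, seed = 12)
  expect_identical(log1, log2)
  expect_equal(nrow(log1), 100)
  expect_s3_class(log1, "session_log")
  oracle <- run_session(conds, omniscient_observer(), 60, seed = 5)
  expect_equal(mean(oracle$correct), 1)
})

test_that("invalid observer responses are logged, not scored", {
  broken <- observer_model("broken", function(v) 7L, needs = "none")
  conds <- list(list(label = "notch_19", param = 19,
                     standard = std_exp1, comparison = cmp_exp1))
  log <- run_session(conds, broken, 10, seed = 2)
  expect_true(all(!log$valid))
  expect_true(all(is.na(log$correct)))
})

test_that("interleaved sessions mix conditions; blocked sessions do not", {
  conds <- experiment_conditions(1)[c(1, 7)]
  li <- run_session(conds, observer_guessing(), 50, seed = 9, order = "interleaved")
  lb <- run_session(conds, observer_guessing(), 50, seed = 9, order = "blocked")
  expect_gt(length(rle(li$condition)$lengths), 10)
  expect_equal(length(rle(lb$condition)$lengths), 2)
  expect_equal(unname(table(li$condition)), unname(table(lb$condition)))
})
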