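# Performance summaries, psychometric fitting, thresholds, bootstrap.

fake_log <- function(params, n, k, task = "dmax") {
  # build a session_log-shaped frame with known counts per condition
  do.call(rbind, Map(function(p, nn, kk) {
    data.frame(trial_id = seq_len(nn), task = task, condition = paste0("c", p),
               param = p, answer = "left",
               choice = c(rep("left", kk), rep("right", nn - kk)),
               correct = c(rep(TRUE, kk), rep(FALSE, nn - kk)), valid = TRUE)
  }, params, n, k))
}

test_that("summaries use exact counts and the closed-form binomial SE", {
  log <- fake_log(1, 280, 140)
  tab <- summarize_session(log)
  expect_equal(tab$proportion_correct, 0.5)
  expect_equal(tab$se, sqrt(0.25 / 280), tolerance = 1e-12)
  expect_equal(tab$se, 0.029881, tolerance = 1e-4)
  all_right <- summarize_session(fake_log(2, 100, 100))
  expect_equal(all_right$proportion_correct, 1)
  expect_equal(all_right$se, 0)
  # integer-exact proportions at large counts
  big <- summarize_session(fake_log(3, 1e6, 333333))
  expect_identical(big$n_correct, 333333L)
  expect_equal(big$proportion_correct, 333333 / 1e6, tolerance = 0)
})

test_that("multi-observer tables add an across-observer row with SEM error bars", {
  logs <- list(a = fake_log(1, 100, 40), b = fake_log(1, 100, 60))
  tab <- summarize_session(logs)
  expect_equal(nrow(tab), 3)
  agg <- tab[tab$is_aggregate, ]
  expect_equal(agg$proportion_correct, 0.5)
  expect_equal(agg$se, stats::sd(c(0.4, 0.6)) / sqrt(2))
  expect_identical(agg$observer, "all")
})

test_that("conditions without valid trials are omitted with a warning", {
  log <- fake_log(c(1, 2), c(50, 10), c(25, 5))
  log$valid[log$param == 2] <- FALSE
  expect_warning(tab <- summarize_session(log), "no valid trials")
  expect_equal(nrow(tab), 1)
})

test_that("psychometric fits recover a known generating curve", {
  # binomial data from a known decreasing logistic (guess 1/2, mid 100)
  x <- c(27, 54, 81, 108, 135, 162)
  p_true <- 0.5 + 0.5 * stats::plogis(-(x - 100) / 15)
  set.seed(7)
  k <- stats::rbinom(length(x), 280, p_true)
  tab <- data.frame(param = x, n_trials = 280, n_correct = k,
                    proportion_correct = k / 280)
  fit <- fit_psychometric(tab, family = "logistic", guess = 0.5, criterion = 0.75)
  expect_true(fit$converged)
  expect_true(fit$decreasing)
  expect_false(fit$extrapolated)
  expect_lt(abs(fit$threshold - 100) / 100, 0.05)
  # threshold invariant to stimulus units up to the conversion
  tab_deg <- transform(tab, param = param / 60)
  fit_deg <- fit_psychometric(tab_deg, family = "logistic", guess = 0.5,
                              criterion = 0.75)
  expect_equal(fit_deg$threshold * 60, fit$threshold, tolerance = 1e-3)
})

test_that("rising oddity data fit with a Weibull and a 1/3 guess rate", {
  x <- c(1, 4, 7, 10, 13, 16, 19)
  p_true <- 1/3 + (1 - 1/3) * (1 - exp(-(x / 8)^2))
  set.seed(11)
  k <- stats::rbinom(length(x), 280, p_true)
  tab <- data.frame(param = x, n_trials = 280, n_correct = k,
                    proportion_correct = k / 280)
  fit <- fit_psychometric(tab, family = "weibull", guess = 1/3, criterion = 0.75)
  expect_false(fit$decreasing)
  x75 <- 8 * (-log(1 - (0.75 - 1/3) / (2/3)))^(1/2)   # closed-form truth
  expect_lt(abs(fit$threshold - x75) / x75, 0.1)
})

test_that("degenerate data are flagged rather than silently extrapolated", {
  flat <- data.frame(param = c(10, 20, 30), n_trials = 200,
                     n_correct = c(66, 67, 66))
  flat$proportion_correct <- flat$n_correct / flat$n_trials
  fit <- fit_psychometric(flat, guess = 1/3, criterion = 0.75)
  expect_true(fit$extrapolated)
  step <- data.frame(param = c(10, 20, 30, 40), n_trials = 200,
                     n_correct = c(200, 200, 67, 67))
  step$proportion_correct <- step$n_correct / step$n_trials
  sfit <- fit_psychometric(step, guess = 1/3, criterion = 0.75)
  expect_gt(sfit$threshold, 10)
  expect_lt(sfit$threshold, 30)          # within one level of the step
  expect_error(fit_psychometric(flat, guess = 1/3, criterion = 0.2), "exceed")
  expect_error(fit_psychometric(flat[1:2, ], guess = 1/3), "3 stimulus levels")
})

test_that("highest-passing-level threshold matches its definition", {
  tab <- data.frame(param = c(27, 54, 81, 108), n_trials = 100,
                    n_correct = c(99, 90, 80, 60))
  tab$proportion_correct <- tab$n_correct / tab$n_trials
  expect_equal(threshold_highest_passing(tab, 0.75), 81)
  expect_true(is.na(threshold_highest_passing(tab, 0.999)))
})

test_that("bootstrap intervals cover the estimate and shrink with n", {
  x <- c(27, 54, 81, 108, 135, 162)
  p_true <- 0.5 + 0.5 * stats::plogis(-(x - 100) / 15)
  make_tab <- function(n, seed) {
    set.seed(seed)
    k <- stats::rbinom(length(x), n, p_true)
    data.frame(param = x, n_trials = n, n_correct = k,
               proportion_correct = k / n)
  }
  tab_small <- make_tab(50, 3); tab_big <- make_tab(280, 3)
  fit_small <- fit_psychometric(tab_small, family = "logistic", guess = 0.5)
  fit_big <- fit_psychometric(tab_big, family = "logistic", guess = 0.5)
  ci_small <- bootstrap_ci(tab_small, fit_small, n_boot = 120, seed = 5)
  ci_big <- bootstrap_ci(tab_big, fit_big, n_boot = 120, seed = 5)
  th_s <- ci_small[ci_small$quantity == "threshold", ]
  th_b <- ci_big[ci_big$quantity == "threshold", ]
  expect_true(th_b$lower <= fit_big$threshold && fit_big$threshold <= th_b$upper)
  expect_lt(th_b$upper - th_b$lower, th_s$upper - th_s$lower)
  # degenerate data (every count at ceiling) resample to themselves, so
  # every replicate refit is identical: zero-width intervals
  perf <- data.frame(param = x, n_trials = 100, n_correct = 100,
                     proportion_correct = 1)
  fitd <- fit_psychometric(perf, family = "logistic", guess = 0.5)
  expect_true(fitd$extrapolated)
  cid <- bootstrap_ci(perf, fitd, n_boot = 30, seed = 9)
  sc <- cid[cid$quantity == "scale", ]
  expect_equal(sc$lower, sc$upper, tolerance = 1e-9)
})
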