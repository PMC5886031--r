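# Session logs -> performance tables -> psychometric fits & thresholds.

#' Summarise a session log into a performance table
#'
#' Exact integer counting of correct responses per condition:
#' `proportion_correct = n_correct / n_trials` with binomial standard
#' error `sqrt(p (1 - p) / n)`. Invalid trials are excluded from the
#' proportions and counted separately. When logs from several observers
#' are pooled (a list of logs, or a log with an `observer` column),
#' per-observer rows are kept and an across-observer aggregate is
#' appended whose error is the SEM of the per-observer proportions —
#' the error-bar convention of multi-observer psychophysics plots.
#'
#' @param log a `session_log`, or a named list of them (one per
#'   observer).
#' @return a data frame of class `performance_table` with columns
#'   `observer`, `task`, `condition`, `param`, `n_trials`, `n_correct`,
#'   `n_invalid`, `proportion_correct`, `se` and a logical
#'   `is_aggregate` marking across-observer rows.
#' @export
summarize_session <- function(log) {
  if (is.data.frame(log)) {
    logs <- list(log)
    names(logs) <- attr(log, "observer") %||% "observer1"
  } else {
    logs <- log
    if (is.null(names(logs))) names(logs) <- paste0("observer", seq_along(logs))
  }
  one <- function(lg, who) {
    key <- interaction(lg$task, lg$condition, drop = TRUE)
    rows <- lapply(split(lg, key), function(d) {
      ok <- d$valid
      n <- sum(ok)
      if (n == 0L) {
        warning("condition '", d$condition[1], "' has no valid trials; omitted")
        return(NULL)
      }
      k <- sum(d$correct[ok])
      p <- k / n
      data.frame(observer = who, task = d$task[1], condition = d$condition[1],
                 param = d$param[1], n_trials = n, n_correct = k,
                 n_invalid = sum(!ok), proportion_correct = p,
                 se = sqrt(p * (1 - p) / n), is_aggregate = FALSE)
    })
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  }
  tab <- do.call(rbind, Map(one, logs, names(logs)))
  if (length(logs) > 1L) {
    agg <- lapply(split(tab, interaction(tab$task, tab$condition, drop = TRUE)),
                  function(d) {
                    p <- d$proportion_correct
                    data.frame(observer = "all", task = d$task[1],
                               condition = d$condition[1], param = d$param[1],
                               n_trials = sum(d$n_trials), n_correct = sum(d$n_correct),
                               n_invalid = sum(d$n_invalid),
                               proportion_correct = mean(p),
                               se = stats::sd(p) / sqrt(length(p)),
                               is_aggregate = TRUE)
                  })
    tab <- rbind(tab, do.call(rbind, agg))
  }
  tab <- tab[order(tab$is_aggregate, tab$observer, tab$param), ]
  rownames(tab) <- NULL
  class(tab) <- c("performance_table", "data.frame")
  tab
}

# Psychometric function families. Both map a stimulus level x to
# P(correct) = guess + (1 - guess - lapse) * F(x); F may be increasing
# (oddity performance vs notch width) or decreasing (Dmax accuracy vs
# displacement).
psy_curve <- function(x, family, pars, guess, lapse, decreasing) {
  f <- switch(family,
              weibull = 1 - exp(-(x / pars[1])^pars[2]),
              logistic = stats::plogis((x - pars[1]) / pars[2]))
  if (decreasing) f <- 1 - f
  guess + (1 - guess - lapse) * f
}

psy_quantile <- function(q, family, pars, decreasing) {
  # level x with F(x) = q (q already direction-adjusted)
  if (decreasing) q <- 1 - q
  switch(family,
         weibull = pars[1] * (-log(1 - q))^(1 / pars[2]),
         logistic = pars[1] + pars[2] * stats::qlogis(q))
}

#' Fit a psychometric function to a performance table
#'
#' Maximum-likelihood binomial fit with the guess rate fixed by the task
#' design (1/3 for oddity, 1/2 for Dmax) and a free lapse rate bounded
#' in `[0, lapse_max]`. The curve direction (performance rising or
#' falling with the stimulus level) is detected from the data. The
#' threshold is the stimulus level at which the fitted curve crosses
#' `criterion`; if the criterion is not bracketed by the fitted values
#' at the observed levels the fit is flagged as an extrapolation.
#'
#' @param table a `performance_table` (rows for one observer and task;
#'   aggregate rows are dropped automatically).
#' @param family `"weibull"` (default) or `"logistic"`.
#' @param guess fixed guess rate `gamma`.
#' @param criterion performance criterion defining the threshold
#'   (default 0.75); must exceed `guess`.
#' @param lapse_max upper bound on the lapse rate; `0` fixes the lapse
#'   at zero (appropriate when fitting data from a lapse-free simulated
#'   observer).
#' @return an object of class `psychometric_fit`: list with `family`,
#'   `decreasing`, `guess`, `lapse`, `pars` (location/scale or
#'   alpha/beta), `threshold`, `criterion`, `logLik`, `converged`,
#'   `extrapolated`, and the fitted `table`.
#' @export
fit_psychometric <- function(table, family = c("weibull", "logistic"),
                             guess = 1/3, criterion = 0.75, lapse_max = 0.06) {
  family <- match.arg(family)
  if (criterion <= guess) {
    stop("fit_psychometric(): criterion ", criterion,
         " must exceed the guess rate ", guess)
  }
  tab <- as.data.frame(table)
  if (!is.null(tab$is_aggregate)) tab <- tab[!tab$is_aggregate, ]
  x <- tab$param; n <- tab$n_trials; k <- tab$n_correct
  if (length(unique(x)) < 3L) {
    stop("fit_psychometric(): need at least 3 stimulus levels")
  }
  o <- order(x); x <- x[o]; n <- n[o]; k <- k[o]
  p_obs <- k / n
  decreasing <- stats::sd(p_obs) > 0 && isTRUE(stats::cor(x, p_obs) < 0)
  if (family == "weibull" && any(x <= 0)) {
    stop("fit_psychometric(): Weibull family needs positive stimulus levels")
  }
  free_lapse <- lapse_max > 0
  nll <- function(par) {
    pars <- if (family == "weibull") exp(par[1:2]) else c(par[1], exp(par[2]))
    lapse <- if (free_lapse) par[3] else 0
    p <- psy_curve(x, family, pars, guess, lapse, decreasing)
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(k * log(p) + (n - k) * log(1 - p))
  }
  init <- if (family == "weibull") c(log(stats::median(x)), log(2))
          else c(stats::median(x), log(diff(range(x)) / 4))
  lower <- c(-Inf, -Inf); upper <- c(Inf, Inf)
  if (family == "weibull") { lower[1:2] <- log(c(1e-6, 0.05)); upper[1:2] <- log(c(1e6, 50)) }
  if (free_lapse) { init <- c(init, 0.01); lower <- c(lower, 0); upper <- c(upper, lapse_max) }
  opt <- stats::optim(init, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = 500))
  pars <- if (family == "weibull") exp(opt$par[1:2]) else c(opt$par[1], exp(opt$par[2]))
  lapse <- if (free_lapse) opt$par[3] else 0
  q <- (criterion - guess) / (1 - guess - lapse)
  fitted_p <- psy_curve(x, family, pars, guess, lapse, decreasing)
  extrapolated <- q <= 0 || q >= 1 ||
    criterion > max(fitted_p) + 1e-9 || criterion < min(fitted_p) - 1e-9
  threshold <- if (q > 0 && q < 1) psy_quantile(q, family, pars, decreasing) else NA_real_
  structure(list(family = family, decreasing = decreasing, guess = guess,
                 lapse = lapse, lapse_max = lapse_max, pars = pars, threshold = threshold,
                 criterion = criterion, logLik = -opt$value,
                 converged = opt$convergence == 0, extrapolated = extrapolated,
                 table = data.frame(param = x, n_trials = n, n_correct = k,
                                    observed = p_obs, fitted = fitted_p)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit> ", x$family, if (x$decreasing) " (decreasing)" else "",
      "  guess ", format(x$guess), "  lapse ", signif(x$lapse, 3), "\n", sep = "")
  cat("  threshold @", x$criterion, ":", signif(x$threshold, 5),
      if (x$extrapolated) " [extrapolated]" else "", "\n")
  invisible(x)
}

#' Threshold as the highest level still meeting the criterion
#'
#' A fit-free reading of a declining performance curve: the largest
#' stimulus level whose observed proportion correct is at least
#' `criterion`. Provided alongside [fit_psychometric()] so analyses can
#' state which convention produced a reported threshold.
#'
#' @inheritParams fit_psychometric
#' @return the stimulus level, or `NA` if no level meets the criterion.
#' @export
threshold_highest_passing <- function(table, criterion = 0.75) {
  tab <- as.data.frame(table)
  if (!is.null(tab$is_aggregate)) tab <- tab[!tab$is_aggregate, ]
  ok <- tab$proportion_correct >= criterion
  if (!any(ok)) return(NA_real_)
  max(tab$param[ok])
}

#' Bootstrap confidence intervals for psychometric fit quantities
#'
#' Nonparametric resampling of trials within each condition (equivalent
#' to redrawing each condition's correct count from its empirical
#' binomial), refitting, and taking percentile intervals of the
#' threshold, lapse, and scale parameters.
#'
#' @param table a `performance_table`.
#' @param fit the `psychometric_fit` whose settings are reused.
#' @param n_boot number of bootstrap replicates.
#' @param level confidence level.
#' @param seed optional integer seed.
#' @return a data frame with one row per quantity: `quantity`,
#'   `estimate`, `lower`, `upper`, `n_ok` (replicates with a finite
#'   refit).
#' @export
bootstrap_ci <- function(table, fit, n_boot = 200, level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "psychometric_fit"))
  maybe_seed(seed)
  tab <- as.data.frame(table)
  if (!is.null(tab$is_aggregate)) tab <- tab[!tab$is_aggregate, ]
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 3,
                  dimnames = list(NULL, c("threshold", "scale", "lapse")))
  for (b in seq_len(n_boot)) {
    rb <- tab
    rb$n_correct <- stats::rbinom(nrow(tab), tab$n_trials,
                                  tab$n_correct / tab$n_trials)
    rb$proportion_correct <- rb$n_correct / rb$n_trials
    fb <- try(fit_psychometric(rb, family = fit$family, guess = fit$guess,
                               criterion = fit$criterion,
                               lapse_max = fit$lapse_max %||% 0.06), silent = TRUE)
    if (!inherits(fb, "try-error")) {
      draws[b, ] <- c(fb$threshold, fb$pars[2], fb$lapse)
    }
  }
  alpha <- (1 - level) / 2
  est <- c(threshold = fit$threshold, scale = fit$pars[2], lapse = fit$lapse)
  out <- lapply(colnames(draws), function(qn) {
    v <- draws[, qn]; v <- v[is.finite(v)]
    data.frame(quantity = qn, estimate = unname(est[qn]),
               lower = if (length(v)) unname(stats::quantile(v, alpha)) else NA_real_,
               upper = if (length(v)) unname(stats::quantile(v, 1 - alpha)) else NA_real_,
               n_ok = length(v))
  })
  do.call(rbind, out)
}
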