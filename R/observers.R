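# Model observers. These decision rules stand in for human participants
# so the full stimulus -> task -> analysis pipeline can be exercised and
# its qualitative behaviour tested; none of them is claimed to reproduce
# human percepts. All are stateless across trials (the task gives no
# feedback, so there is nothing to learn from).

#' Construct an observer model
#'
#' An observer is a named decision rule mapping a (blinded) trial view
#' to a response, plus a declaration of how much stimulus data it needs,
#' which lets [run_session()] skip generating data the rule never reads.
#'
#' @param name short identifier.
#' @param fun function of one argument (the trial view) returning a
#'   choice: `1`/`2`/`3` for oddity, `"left"`/`"right"` for Dmax.
#' @param needs one of `"none"` (stimulus-blind), `"speeds"` (per-update
#'   draws), `"full"` (positions too), or `"trial"` (the unblinded
#'   trial; only for calibrated response models that emit a correct
#'   answer with a stated probability).
#' @param params list of model parameters, recorded for metadata.
#' @return an object of class `observer_model`.
#' @export
observer_model <- function(name, fun, needs = c("speeds", "none", "full", "trial"),
                           params = list()) {
  needs <- match.arg(needs)
  stopifnot(is.function(fun))
  structure(list(name = name, fun = fun, needs = needs, params = params),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat("<observer_model>", x$name, " (needs:", x$needs, ")\n")
  if (length(x$params)) utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

#' Guessing observer
#'
#' Chooses an interval uniformly at random, ignoring the stimulus; its
#' long-run accuracy is the 1/3 chance floor of the oddity task.
#'
#' @return an `observer_model`.
#' @export
observer_guessing <- function() {
  observer_model("guess", function(view) sample.int(3L, 1L), needs = "none")
}

#' Largest-gap statistic of a sample
#'
#' The width of the largest empty interval between consecutive sorted
#' unique sample values, after restricting the sample to
#' `[range_lo, range_hi]`. A sample drawn from a notched distribution
#' exposes the notch as a large internal gap; a dense uniform sample has
#' gaps no wider than its grid spacing.
#'
#' @param x numeric sample (at least one value after range restriction).
#' @param range_lo,range_hi restriction range.
#' @return the largest gap (0 for a single distinct value).
#' @export
gap_statistic <- function(x, range_lo = -Inf, range_hi = Inf) {
  if (!length(x)) stop("gap_statistic(): empty sample")
  x <- x[x >= range_lo & x <= range_hi]
  if (!length(x)) stop("gap_statistic(): no sample values inside the range")
  u <- sort(unique(x))
  if (length(u) < 2L) return(0)
  max(diff(u))
}

#' Odd-one-out decision from three interval statistics
#'
#' Chooses the interval whose statistic is most distant from the other
#' two (maximal summed absolute difference); exact ties are broken
#' uniformly at random.
#'
#' @param stats numeric vector of three finite statistics.
#' @return an integer choice in `1:3`.
#' @export
oddity_decision <- function(stats) {
  stopifnot(length(stats) == 3L, all(is.finite(stats)))
  d <- vapply(1:3, function(i) sum(abs(stats[i] - stats[-i])), 0)
  cand <- which(d >= max(d) - 1e-12)
  if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
}

# Pool the per-update draws of one interval into a flat sample.
interval_sample <- function(view, i, what = c("speeds", "directions")) {
  what <- match.arg(what)
  m <- view$intervals[[i]][[what]]
  if (is.null(m)) stop("observer needs interval ", what, " but the trial has none")
  as.vector(m)
}

#' Noisy speed-gap observer
#'
#' Perceives each sampled dot speed with multiplicative (Weber-like)
#' Gaussian noise, `perceived = speed * (1 + N(0, noise_fraction))`,
#' computes the largest-gap statistic of each interval's perceived
#' speeds within the trial's declared range, and picks the odd interval
#' with [oddity_decision()]. With `noise_fraction = 0` this is the
#' noiseless gap oracle. Because the noise scales with speed, a notch of
#' fixed width is progressively obscured at faster absolute speeds — the
#' mechanism by which this model family loses the notch in fast-range
#' conditions while retaining it in slow-range ones.
#'
#' @param noise_fraction standard deviation of the proportional speed
#'   noise (dimensionless).
#' @return an `observer_model`.
#' @export
observer_speed_gap <- function(noise_fraction = 0) {
  stopifnot(noise_fraction >= 0)
  fun <- function(view) {
    g <- vapply(1:3, function(i) {
      s <- interval_sample(view, i, "speeds")
      if (noise_fraction > 0) s <- s * (1 + stats::rnorm(length(s), 0, noise_fraction))
      gap_statistic(s, view$range[1], view$range[2])
    }, 0)
    oddity_decision(g)
  }
  observer_model(if (noise_fraction == 0) "gap-oracle" else "noisy-speed",
                 fun, needs = "speeds",
                 params = list(noise_fraction = noise_fraction))
}

#' Noisy direction-gap observer
#'
#' The direction analogue of [observer_speed_gap()]: perceived dot
#' directions are jittered by additive Gaussian noise (deg), optionally
#' scaled with the trial's fixed dot speed, and the largest directional
#' gap decides the odd interval.
#'
#' @param direction_noise_deg standard deviation of the direction noise
#'   at the reference speed (deg).
#' @param speed_scaling if `TRUE`, the noise s.d. is multiplied by
#'   `trial_speed / reference_speed`, so faster stimuli are judged with
#'   proportionally noisier directions.
#' @param reference_speed speed (deg/s) at which the nominal noise
#'   applies.
#' @return an `observer_model`.
#' @export
observer_direction_gap <- function(direction_noise_deg = 0, speed_scaling = FALSE,
                                   reference_speed = 4) {
  stopifnot(direction_noise_deg >= 0, reference_speed > 0)
  fun <- function(view) {
    sd_deg <- direction_noise_deg
    if (speed_scaling && is.finite(view$trial_speed)) {
      sd_deg <- sd_deg * view$trial_speed / reference_speed
    }
    g <- vapply(1:3, function(i) {
      d <- interval_sample(view, i, "directions")
      if (sd_deg > 0) d <- d + stats::rnorm(length(d), 0, sd_deg)
      gap_statistic(d, view$range[1] - 3 * sd_deg, view$range[2] + 3 * sd_deg)
    }, 0)
    oddity_decision(g)
  }
  observer_model("direction-gap", fun, needs = "speeds",
                 params = list(direction_noise_deg = direction_noise_deg,
                               speed_scaling = speed_scaling,
                               reference_speed = reference_speed))
}

#' Calibrated Dmax response model
#'
#' Responds correctly with a probability that declines logistically in
#' the trial displacement: `p(d) = 0.5 + 0.5 * plogis(-(d - limit) /
#' slope)`, so accuracy is 0.75 exactly at `d = limit` and approaches
#' the 0.5 guessing floor for large displacements. This is a response
#' simulator for threshold-recovery tests, not a perceptual model — it
#' reads the trial's true direction in order to emit a correct response
#' at the calibrated rate (hence `needs = "trial"`).
#'
#' @param displacement_limit the displacement (arc min) at which
#'   accuracy is 75%.
#' @param slope logistic scale (arc min).
#' @return an `observer_model`.
#' @export
observer_dmax <- function(displacement_limit = 100, slope = 15) {
  stopifnot(displacement_limit > 0, slope > 0)
  fun <- function(trial) {
    p <- 0.5 + 0.5 * stats::plogis(-(trial$dmax_displacement - displacement_limit) / slope)
    if (stats::runif(1) <= p) trial$dmax_direction
    else setdiff(c("left", "right"), trial$dmax_direction)
  }
  observer_model("dmax-logistic", fun, needs = "trial",
                 params = list(displacement_limit = displacement_limit, slope = slope))
}
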