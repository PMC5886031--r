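# Trial assembly and session running: 3AFC oddity trials, single-interval
# Dmax trials, and reproducible session logs.

#' Assemble one 3AFC odd-one-out trial
#'
#' Three intervals in random order: two independent samples of the
#' standard and one comparison, placed at a uniformly random position.
#' For speed distributions all three intervals share a trial direction
#' drawn uniformly from [0, 360); for direction distributions all three
#' share a fixed trial speed.
#'
#' @param standard,comparison matched `discrete_distribution`s (checked
#'   with [validate_matched()]).
#' @param spec a [stimulus_spec()].
#' @param trial_speed fixed dot speed (deg/s), required for direction
#'   distributions.
#' @param detail how much interval data to generate: `"speeds"`
#'   (per-update draws only, sufficient for sample-based observers),
#'   `"full"` (positions too), or `"none"` (no interval data; for
#'   stimulus-blind observers such as the guessing model).
#' @param seed optional integer seed.
#' @return an object of class `rdk_trial` with fields `task`
#'   (`"oddity"`), `kind`, `intervals`, `odd_index`, `trial_direction`
#'   or `trial_speed`, and `range`.
#' @export
make_oddity_trial <- function(standard, comparison, spec = stimulus_spec(),
                              trial_speed = NULL,
                              detail = c("speeds", "full", "none"), seed = NULL) {
  detail <- match.arg(detail)
  rep_ <- validate_matched(standard, comparison)
  if (!rep_$pass) {
    stop("make_oddity_trial(): standard and comparison are not statistics-matched:\n",
         paste(utils::capture.output(print(rep_$checks)), collapse = "\n"))
  }
  maybe_seed(seed)
  kind <- standard$kind
  odd_index <- sample.int(3L, 1L)
  trial_direction <- NA_real_
  if (kind == "speed") {
    trial_direction <- stats::runif(1, 0, 360)
    speed_sources <- list(standard, standard, standard)
    speed_sources[[odd_index]] <- comparison
    dir_source <- trial_direction
    make_one <- function(i) generate_interval(spec, speed_sources[[i]], dir_source,
                                              positions = (detail == "full"))
  } else {
    if (is.null(trial_speed)) {
      stop("make_oddity_trial(): direction trials need a fixed trial_speed")
    }
    dir_sources <- list(standard, standard, standard)
    dir_sources[[odd_index]] <- comparison
    make_one <- function(i) generate_interval(spec, trial_speed, dir_sources[[i]],
                                              positions = (detail == "full"))
  }
  intervals <- if (detail == "none") NULL else lapply(1:3, make_one)
  structure(list(task = "oddity", kind = kind, intervals = intervals,
                 odd_index = odd_index, trial_direction = trial_direction,
                 trial_speed = trial_speed %||% NA_real_,
                 range = c(standard$range_lo, standard$range_hi),
                 spec = spec),
            class = "rdk_trial")
}

#' Assemble one Dmax direction-discrimination trial
#'
#' A single interval in which every dot moves by the same displacement
#' on every update, all leftwards or all rightwards (chosen at random).
#'
#' @param displacement_arcmin common per-update displacement (arc min).
#' @param spec a [stimulus_spec()].
#' @param detail `"none"` (default; the calibrated Dmax response model
#'   needs only the displacement), `"speeds"`, or `"full"`.
#' @param seed optional integer seed.
#' @return an `rdk_trial` with `task = "dmax"`, `dmax_displacement`
#'   (arc min), `dmax_displacement_deg`, and `dmax_direction`
#'   (`"left"` or `"right"`).
#' @export
make_dmax_trial <- function(displacement_arcmin, spec = stimulus_spec(),
                            detail = c("none", "speeds", "full"), seed = NULL) {
  detail <- match.arg(detail)
  stopifnot(displacement_arcmin >= 0)
  maybe_seed(seed)
  direction <- if (stats::runif(1) < 0.5) "left" else "right"
  disp_deg <- arcmin_to_deg(displacement_arcmin)
  speed <- disp_deg * spec$update_rate
  interval <- if (detail == "none") NULL else {
    list(generate_interval(spec, speed,
                           if (direction == "right") 0 else 180,
                           positions = (detail == "full")))
  }
  structure(list(task = "dmax", kind = "speed", intervals = interval,
                 dmax_displacement = displacement_arcmin,
                 dmax_displacement_deg = disp_deg,
                 dmax_direction = direction, spec = spec),
            class = "rdk_trial")
}

#' Blinded observer view of a trial
#'
#' Strips the ground truth (`odd_index`, `dmax_direction`) from a trial
#' so observers can only use stimulus data. Calibrated response models
#' declared with `needs = "trial"` bypass this (they emit a correct
#' response with a stated probability and therefore require the truth).
#'
#' @param trial an `rdk_trial`.
#' @return the trial without its answer fields.
#' @export
observer_view <- function(trial) {
  trial$odd_index <- NULL
  trial$dmax_direction <- NULL
  trial
}

trial_answer <- function(trial) {
  if (trial$task == "oddity") as.character(trial$odd_index) else trial$dmax_direction
}

valid_choices <- function(trial) {
  if (trial$task == "oddity") c("1", "2", "3") else c("left", "right")
}

#' Run a simulated session
#'
#' Presents every condition `n_trials_per_condition` times to an
#' observer, in interleaved (randomised) or blocked order, and logs one
#' row per trial. No feedback of any kind reaches the observer. An
#' observer response outside the valid set is logged as a protocol
#' violation (`valid = FALSE`, `correct = NA`) rather than silently
#' scored.
#'
#' @param conditions a list of condition descriptions. Oddity condition:
#'   `list(label =, param =, standard =, comparison =, trial_speed = NULL)`.
#'   Dmax condition: `list(task = "dmax", label =, param =,
#'   displacement =)`. See [experiment_conditions()].
#' @param observer an [observer_model()].
#' @param n_trials_per_condition trials per condition (the study design
#'   used a minimum of 280).
#' @param spec a [stimulus_spec()].
#' @param seed master seed; the session is fully reproducible from
#'   `(conditions, observer, seed)`.
#' @param order `"interleaved"` (default) or `"blocked"` condition order.
#' @return a data frame of class `session_log` with columns `trial_id`,
#'   `task`, `condition`, `param`, `answer`, `choice`, `correct`,
#'   `valid`, plus attributes `seed` and `observer`.
#' @export
run_session <- function(conditions, observer, n_trials_per_condition = 280,
                        spec = stimulus_spec(), seed = NULL,
                        order = c("interleaved", "blocked")) {
  order <- match.arg(order)
  stopifnot(inherits(observer, "observer_model"), length(conditions) >= 1L)
  if (!is.null(seed)) set.seed(derive_seed(seed, "session"))
  ncond <- length(conditions)
  sched <- rep(seq_len(ncond), each = n_trials_per_condition)
  if (order == "interleaved") sched <- sample(sched)
  n <- length(sched)
  detail <- switch(observer$needs,
                   none = "none", trial = "none", speeds = "speeds", full = "full")
  lab <- vapply(conditions, function(cc) as.character(cc$label %||% cc$param), "")
  par <- vapply(conditions, function(cc) as.numeric(cc$param %||% NA_real_), 0)
  tasks <- vapply(conditions, function(cc) cc$task %||% "oddity", "")
  answer <- character(n); choice <- character(n); valid <- logical(n)
  for (i in seq_len(n)) {
    cc <- conditions[[sched[i]]]
    trial <- if (tasks[sched[i]] == "dmax") {
      make_dmax_trial(cc$displacement, spec, detail = detail)
    } else {
      make_oddity_trial(cc$standard, cc$comparison, spec,
                        trial_speed = cc$trial_speed, detail = detail)
    }
    seen <- if (observer$needs == "trial") trial else observer_view(trial)
    resp <- as.character(observer$fun(seen))
    answer[i] <- trial_answer(trial)
    choice[i] <- resp
    valid[i] <- length(resp) == 1L && resp %in% valid_choices(trial)
  }
  log <- data.frame(trial_id = seq_len(n), task = tasks[sched],
                    condition = lab[sched], param = par[sched],
                    answer = answer, choice = choice,
                    correct = ifelse(valid, answer == choice, NA),
                    valid = valid)
  attr(log, "seed") <- seed
  attr(log, "observer") <- observer$name
  class(log) <- c("session_log", "data.frame")
  log
}
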