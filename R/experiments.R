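# The four experiment families, with their printed parameter sets as
# defaults, expressed as condition lists consumable by run_session().

#' Default parameters of the four experiment families
#'
#' @return a nested list of the configured parameter enumerations:
#'   notch widths, mean distances, bandwidths, slow/fast ranges and
#'   notch widths, directional gaps and fixed speeds, plus grid
#'   intervals and the shared global-mean / range constants.
#' @export
experiment_defaults <- function() {
  list(
    exp1 = list(range = c(0.4, 23.6), interval = 1,
                notch_widths = c(1, 4, 7, 10, 13, 16, 19)),
    exp2_means = list(band_range = 8.1, notch_width = 7, global_mean = 12,
                      interval = 0.2, mean_distances = c(13, 14, 15, 16, 17)),
    exp2_bandwidth = list(notch_width = 7, global_mean = 12, interval = 0.2,
                          bandwidths = c(8, 11, 14, 17, 20)),
    exp3 = list(slow_range = c(1.2, 8), fast_range = c(17.2, 24), interval = 0.4,
                notch_widths = c(1.2, 2, 3.6, 5.2), mean_distance = 6),
    exp4 = list(span = 58, mean_dir = 30, interval = 1,
                gap_widths = c(2, 10, 18, 26, 34, 42, 50),
                speeds = c(4, 13, 22)),
    dmax = list(displacements = c(27, 54, 81, 108, 135, 162))
  )
}

#' Build the condition list for an experiment family
#'
#' Constructs the standard and every comparison distribution of one
#' experiment family and packages them as conditions for
#' [run_session()]. Every standard/comparison pair is verified to be
#' statistics-matched before it is returned.
#'
#' @param experiment experiment id, 1-4, or `"dmax"`.
#' @param variant for experiment 2, `"means"` (mean-distance family) or
#'   `"bandwidth"`; for experiment 3, `"slow"` or `"fast"`.
#' @param trial_speed for experiment 4, the fixed dot speed (deg/s),
#'   one of 4, 13, 22 by default.
#' @param params overrides for the defaults of
#'   [experiment_defaults()] (same field names).
#' @return a list of condition lists, each with `label`, `param`, and
#'   either `standard` + `comparison` (+ `trial_speed`) or, for
#'   `"dmax"`, `task = "dmax"` and `displacement`.
#' @examples
#' conds <- experiment_conditions(1)
#' length(conds)                       # one condition per notch width
#' conds[[7]]$comparison$support      # the 19-deg/s-notch comparison
#' @export
experiment_conditions <- function(experiment, variant = NULL, trial_speed = NULL,
                                  params = list()) {
  def <- utils::modifyList(experiment_defaults(), params)
  oddity_cond <- function(param, standard, comparison, label, speed = NULL) {
    stopifnot(validate_matched(standard, comparison)$pass)
    list(label = label, param = param, standard = standard,
         comparison = comparison, trial_speed = speed)
  }
  if (identical(experiment, "dmax")) {
    return(lapply(def$dmax$displacements, function(d) {
      list(task = "dmax", label = paste0("dmax_", d), param = d, displacement = d)
    }))
  }
  experiment <- as.integer(experiment)
  if (experiment == 1L) {
    e <- def$exp1
    std <- build_uniform(e$range[1], e$range[2], e$interval)
    return(lapply(e$notch_widths, function(w) {
      oddity_cond(w, std, build_symmetric_notched(e$range[1], e$range[2], w, e$interval),
                  label = paste0("notch_", w))
    }))
  }
  if (experiment == 2L) {
    variant <- match.arg(variant, c("means", "bandwidth"))
    if (variant == "means") {
      e <- def$exp2_means
      span <- 2 * e$band_range + e$notch_width
      std <- build_uniform(e$global_mean - span / 2, e$global_mean + span / 2, e$interval)
      return(lapply(e$mean_distances, function(d) {
        oddity_cond(d, std,
                    build_mean_targeted_notched(d, e$band_range, e$notch_width,
                                                e$global_mean, e$interval),
                    label = paste0("meandist_", d))
      }))
    }
    e <- def$exp2_bandwidth
    return(lapply(e$bandwidths, function(bw) {
      fam <- build_bandwidth_family(bw, e$notch_width, e$global_mean, e$interval)
      oddity_cond(bw, fam$standard, fam$comparison, label = paste0("bandwidth_", bw))
    }))
  }
  if (experiment == 3L) {
    variant <- match.arg(variant, c("slow", "fast"))
    e <- def$exp3
    rng <- if (variant == "slow") e$slow_range else e$fast_range
    std <- build_uniform(rng[1], rng[2], e$interval)
    return(lapply(e$notch_widths, function(w) {
      oddity_cond(w, std,
                  build_constant_distance_notched(rng[1], rng[2], w,
                                                  e$mean_distance, e$interval),
                  label = paste0(variant, "_notch_", w))
    }))
  }
  if (experiment == 4L) {
    e <- def$exp4
    speed <- trial_speed %||% e$speeds[1]
    std <- build_direction_gapped(e$span, e$mean_dir, 0, e$interval)
    return(lapply(e$gap_widths, function(g) {
      oddity_cond(g, std, build_direction_gapped(e$span, e$mean_dir, g, e$interval),
                  label = paste0("gap_", g, "_speed_", speed), speed = speed)
    }))
  }
  stop("experiment_conditions(): unknown experiment '", experiment, "'")
}
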