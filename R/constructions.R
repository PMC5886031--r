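# Higher-level distribution constructions: mean-distance families,
# bandwidth families, constant-mean-distance notches, and directional
# gaps. All reuse the band-gridding convention of distributions.R and
# the exponential-tilt solver for mean control.

#' Comparison distribution with a targeted distance between band means
#'
#' Two bands of fixed width separated by a fixed notch, with per-band
#' sampling densities (exponential-tilt weights) chosen so the local
#' band means sit at `global_mean -/+ target_mean_distance / 2`. Each
#' band carries probability mass 1/2, so the global mean stays at
#' `global_mean` regardless of the targeted distance. Each band's grid
#' is anchored at both of its endpoints (the outer range endpoint and
#' the notch edge), which keeps the band width and the notch width at
#' exactly their configured values even when the band width is not a
#' whole multiple of the grid spacing — as with the default 8.1-deg/s
#' bands.
#'
#' @param target_mean_distance desired distance between the two band
#'   means (deg/s).
#' @param band_range width of each band (deg/s); default 8.1.
#' @param notch_width central excluded interval (deg/s); default 7.
#' @param global_mean shared global mean of standard and comparison
#'   (deg/s); default 12.
#' @param interval grid spacing inside each band (deg/s); default 0.2.
#' @param tolerance mean-constraint tolerance passed to
#'   [solve_band_tilt()].
#' @return a `discrete_distribution` spanning
#'   `2 * band_range + notch_width`.
#' @examples
#' d <- build_mean_targeted_notched(13)
#' moments(d)$band_means     # 5.5 and 18.5
#' @export
build_mean_targeted_notched <- function(target_mean_distance, band_range = 8.1,
                                        notch_width = 7, global_mean = 12,
                                        interval = 0.2, tolerance = 1e-6) {
  stopifnot(band_range > 0, notch_width >= 0)
  range_lo <- global_mean - notch_width / 2 - band_range
  range_hi <- global_mean + notch_width / 2 + band_range
  notch <- c(global_mean - notch_width / 2, global_mean + notch_width / 2)
  bg <- list(lower = dual_grid(range_lo, notch[1], interval),
             upper = dual_grid(notch[2], range_hi, interval))
  targets <- global_mean + c(-1, 1) * target_mean_distance / 2
  check_band_target(bg$lower, targets[1], "lower")
  check_band_target(bg$upper, targets[2], "upper")
  tl <- solve_band_tilt(bg$lower, targets[1], tolerance)
  tu <- solve_band_tilt(bg$upper, targets[2], tolerance)
  dist <- discrete_distribution(
    c(bg$lower, bg$upper), c(tl$weights, tu$weights) / 2,
    kind = "speed", range_lo = range_lo, range_hi = range_hi,
    interval = interval, notch = notch,
    tilt = list(lambda = c(tl$lambda, tu$lambda), targets = targets))
  gm <- moments(dist)$global_mean
  if (abs(gm - global_mean) > 1e-6) {
    stop("build_mean_targeted_notched(): global mean ", gm, " misses ", global_mean)
  }
  dist
}

check_band_target <- function(band, target, which) {
  if (target <= min(band) || target >= max(band)) {
    stop("infeasible constraint: target ", which, "-band mean ", target,
         " lies outside the band (", min(band), ", ", max(band), ")")
  }
  invisible(NULL)
}

#' Standard / comparison pair for a given speed bandwidth
#'
#' The bandwidth family varies the total range of speeds while keeping
#' the notch width and the global mean fixed: the standard is uniform
#' over `global_mean +/- total_span / 2` and the comparison is the
#' symmetric-notch construction over the same span.
#'
#' @param total_span full range of speeds (deg/s); must exceed
#'   `notch_width`.
#' @param notch_width comparison notch (deg/s); default 7.
#' @param global_mean shared mean (deg/s); default 12.
#' @param interval grid spacing (deg/s).
#' @return a list with elements `standard` and `comparison`.
#' @export
build_bandwidth_family <- function(total_span, notch_width = 7, global_mean = 12,
                                   interval = 1) {
  stopifnot(total_span > 0)
  if (total_span <= notch_width + GRID_TOL) {
    stop("build_bandwidth_family(): total span ", total_span,
         " does not exceed the notch width ", notch_width, " (empty bands)")
  }
  lo <- global_mean - total_span / 2
  hi <- global_mean + total_span / 2
  # bands anchored at both their endpoints: the notch width is a
  # controlled constant of this family and must stay exactly at its
  # configured value for every bandwidth
  list(standard = build_uniform(lo, hi, interval),
       comparison = build_symmetric_notched(lo, hi, notch_width, interval,
                                            band_anchor = "both"))
}

#' Comparison distributions with constant distance between band means
#'
#' Varies the notch width while holding the distance between the two
#' local band means fixed: bands are anchored at the outer range
#' endpoints with a centred notch, and per-band exponential-tilt weights
#' move each band mean to `midpoint -/+ mean_distance / 2`. Each band
#' carries mass 1/2, so the global mean equals the range midpoint for
#' every notch width.
#'
#' @inheritParams build_symmetric_notched
#' @param mean_distance fixed distance between band means (deg/s); must
#'   be at least `notch_width` and feasible for both bands.
#' @param tolerance mean-constraint tolerance.
#' @return a `discrete_distribution`.
#' @examples
#' d <- build_constant_distance_notched(1.2, 8, 2, 6, 0.4)
#' moments(d)$mean_distance   # 6 for every notch width
#' @export
build_constant_distance_notched <- function(range_lo, range_hi, notch_width,
                                            mean_distance = 6, interval = 0.4,
                                            tolerance = 1e-6) {
  stopifnot(notch_width > 0, mean_distance > 0)
  if (mean_distance < notch_width) {
    stop("infeasible constraint: mean distance ", mean_distance,
         " is smaller than the notch width ", notch_width,
         " (band means would fall inside the notch)")
  }
  span <- range_hi - range_lo
  if (notch_width >= span - GRID_TOL) {
    stop("build_constant_distance_notched(): notch width ", notch_width,
         " leaves no room inside the range span ", span)
  }
  mid <- (range_lo + range_hi) / 2
  notch <- c(mid - notch_width / 2, mid + notch_width / 2)
  bg <- band_grids(range_lo, range_hi, notch[1], notch[2], interval)
  targets <- mid + c(-1, 1) * mean_distance / 2
  feasible <- function(band, target) target > min(band) - GRID_TOL &&
    target < max(band) + GRID_TOL
  if (!feasible(bg$lower, targets[1]) || !feasible(bg$upper, targets[2])) {
    stop("infeasible constraint: mean distance ", mean_distance,
         " forces band means (", targets[1], ", ", targets[2],
         ") outside the bands [", min(bg$lower), ", ", max(bg$lower), "] and [",
         min(bg$upper), ", ", max(bg$upper), "]")
  }
  tl <- solve_band_tilt(bg$lower, targets[1], tolerance)
  tu <- solve_band_tilt(bg$upper, targets[2], tolerance)
  dist <- discrete_distribution(
    c(bg$lower, bg$upper), c(tl$weights, tu$weights) / 2,
    kind = "speed", range_lo = range_lo, range_hi = range_hi,
    interval = interval, notch = notch,
    tilt = list(lambda = c(tl$lambda, tu$lambda), targets = targets))
  gm <- moments(dist)$global_mean
  if (abs(gm - mid) > 1e-6) {
    stop("build_constant_distance_notched(): global mean ", gm, " misses ", mid)
  }
  dist
}

#' Direction distribution with a symmetric directional gap
#'
#' The direction analogue of the symmetric speed notch: a uniform
#' distribution of directions spanning `span` degrees centred on
#' `mean_dir`, with a gap of `gap_width` degrees carved out around the
#' mean. A zero gap returns the standard. Direction arithmetic is
#' linear; supports here span well under a half-circle, and any global
#' rotation of the stimulus is applied modulo 360 at trial level.
#'
#' @param span full range of directions (deg); default 58.
#' @param mean_dir centre direction (deg); default 30.
#' @param gap_width directional gap (deg); must be smaller than `span`.
#' @param interval grid spacing (deg); default 1.
#' @return a `discrete_distribution` of kind `"direction"`.
#' @export
build_direction_gapped <- function(span = 58, mean_dir = 30, gap_width = 0,
                                   interval = 1) {
  stopifnot(span > 0, gap_width >= 0)
  if (gap_width >= span - GRID_TOL) {
    stop("build_direction_gapped(): gap width ", gap_width,
         " must be smaller than the span ", span)
  }
  lo <- mean_dir - span / 2
  hi <- mean_dir + span / 2
  build_symmetric_notched(lo, hi, gap_width, interval, kind = "direction")
}
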