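# Frame-by-frame dot kinematics. Dot positions are continuous degrees
# relative to the aperture centre; pixel quantisation happens only in
# rasterize().

#' Stimulus geometry and timing
#'
#' Bundles the geometry/timing constants of one RDK interval. Defaults
#' are the study conditions: 226 dots in a 12-deg circular aperture
#' (2 dots/deg^2), 0.1-deg dots, 10 images at an 18.75-Hz update rate
#' (every 4th frame of a 75-Hz display), 500-ms inter-stimulus interval.
#'
#' @param n_dots number of dots per image.
#' @param aperture_diameter aperture diameter (deg).
#' @param dot_diameter dot diameter (deg).
#' @param dot_luminance,background_luminance luminances (cd/m^2);
#'   metadata used by [rasterize()].
#' @param update_rate positional update rate (Hz).
#' @param n_updates number of images per interval.
#' @param isi_ms inter-stimulus interval (ms); metadata.
#' @param monitor_refresh display refresh (Hz); metadata. A warning is
#'   issued if the update rate does not divide it.
#' @param dot_density declared dot density (dots/deg^2) checked against
#'   `n_dots` and the aperture area within 1%, or `NULL` to skip.
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(n_dots = 226, aperture_diameter = 12, dot_diameter = 0.1,
                          dot_luminance = 0.05, background_luminance = 25,
                          update_rate = 18.75, n_updates = 10, isi_ms = 500,
                          monitor_refresh = 75, dot_density = 2) {
  stopifnot(n_dots >= 1, aperture_diameter > 0, dot_diameter > 0,
            update_rate > 0, n_updates >= 1)
  area <- pi * (aperture_diameter / 2)^2
  if (!is.null(dot_density)) {
    got <- n_dots / area
    if (abs(got - dot_density) > 0.01 * dot_density) {
      stop("stimulus_spec(): ", n_dots, " dots in a ", aperture_diameter,
           "-deg aperture give ", signif(got, 4), " dots/deg^2, not the declared ",
           dot_density)
    }
  }
  ratio <- monitor_refresh / update_rate
  if (abs(ratio - round(ratio)) > 1e-9) {
    warning("update rate ", update_rate, " Hz does not divide the monitor refresh ",
            monitor_refresh, " Hz")
  }
  structure(list(n_dots = as.integer(n_dots), aperture_diameter = aperture_diameter,
                 dot_diameter = dot_diameter, dot_luminance = dot_luminance,
                 background_luminance = background_luminance,
                 update_rate = update_rate, n_updates = as.integer(n_updates),
                 isi_ms = isi_ms, monitor_refresh = monitor_refresh,
                 dot_density = dot_density),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("<stimulus_spec> ", x$n_dots, " dots, ", x$aperture_diameter,
      "-deg aperture, ", x$n_updates, " images @ ", x$update_rate, " Hz (",
      round(1000 * x$n_updates / x$update_rate, 1), " ms)\n", sep = "")
  invisible(x)
}

#' Per-update displacement of a dot moving at a given speed
#'
#' `displacement = speed / update_rate`, exact. At the default 18.75-Hz
#' update rate a 31.25 deg/s dot moves 5/3 deg (100 arc min) per update.
#'
#' @param speed dot speed (deg/s), nonnegative.
#' @param update_rate positional update rate (Hz).
#' @return displacement per update (deg).
#' @export
speed_to_displacement <- function(speed, update_rate = 18.75) {
  if (any(speed < 0)) stop("speed_to_displacement(): negative speed")
  stopifnot(update_rate > 0)
  speed / update_rate
}

#' Initialise a dot field uniformly over the aperture disk
#'
#' Positions are uniform over the disk *area* (radius drawn as
#' `R * sqrt(u)`), not uniform in radius.
#'
#' @param spec a [stimulus_spec()].
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `dot_field`: list with numeric vectors
#'   `x`, `y` (deg) and `current_speeds`, `current_directions` (NA until
#'   the first update).
#' @export
init_dot_field <- function(spec = stimulus_spec(), seed = NULL) {
  maybe_seed(seed)
  n <- spec$n_dots
  r <- (spec$aperture_diameter / 2) * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  structure(list(x = r * cos(th), y = r * sin(th),
                 current_speeds = rep(NA_real_, n),
                 current_directions = rep(NA_real_, n)),
            class = "dot_field")
}

#' Wrap proposed dot positions back into the aperture
#'
#' A dot whose proposed position falls outside the circular window is
#' redrawn on the opposite side: the proposal is reflected through the
#' aperture centre and radially clamped to lie just inside the rim.
#' In-aperture proposals are returned unchanged.
#'
#' @param x,y proposed positions (deg), vectorised.
#' @param aperture_radius aperture radius (deg).
#' @return a list with wrapped `x` and `y`; every result satisfies
#'   `sqrt(x^2 + y^2) <= aperture_radius`.
#' @export
wrap_position <- function(x, y, aperture_radius) {
  r <- sqrt(x^2 + y^2)
  out <- which(r > aperture_radius)
  if (length(out)) {
    f <- -(aperture_radius * (1 - 1e-12)) / r[out]  # reflect + clamp to the rim
    x[out] <- x[out] * f
    y[out] <- y[out] * f
  }
  list(x = x, y = y)
}

# Resolve a motion source to per-dot draws. A source is either a
# discrete_distribution (resampled per dot per update) or a single fixed
# value held for the whole interval.
draw_source <- function(source, n) {
  if (is_discrete_distribution(source)) {
    sample_values(source$support, n, source$probabilities)
  } else if (is.numeric(source) && length(source) == 1L) {
    rep.int(source, n)
  } else {
    stop("motion source must be a discrete_distribution or a single number")
  }
}

#' Advance a dot field by one positional update
#'
#' Each dot independently draws a fresh speed (or direction) from its
#' source on every update — dot speed performs a random walk over the
#' interval rather than staying fixed — then moves along its direction
#' by `speed / update_rate` and is wrapped back into the aperture.
#' Exactly one of the two sources may be a distribution: speed
#' experiments fix the direction within a trial, the direction
#' experiment fixes the speed.
#'
#' @param field a `dot_field`.
#' @param speed_source a speed `discrete_distribution` or a fixed speed
#'   (deg/s).
#' @param direction_source a direction `discrete_distribution` or a
#'   fixed direction (deg, 0 = rightward, counterclockwise).
#' @param spec a [stimulus_spec()].
#' @return the advanced `dot_field` with `current_speeds` and
#'   `current_directions` set to this update's draws.
#' @export
advance <- function(field, speed_source, direction_source, spec = stimulus_spec()) {
  stopifnot(inherits(field, "dot_field"))
  if (is_discrete_distribution(speed_source) && speed_source$kind != "speed") {
    stop("advance(): speed_source has kind '", speed_source$kind, "'")
  }
  if (is_discrete_distribution(direction_source) && direction_source$kind != "direction") {
    stop("advance(): direction_source has kind '", direction_source$kind, "'")
  }
  if (is_discrete_distribution(speed_source) && is_discrete_distribution(direction_source)) {
    stop("advance(): only one of speed and direction may vary within an interval")
  }
  n <- length(field$x)
  sp <- draw_source(speed_source, n)
  dr <- draw_source(direction_source, n)
  d <- sp / spec$update_rate
  w <- wrap_position(field$x + d * cos(dr * pi / 180),
                     field$y + d * sin(dr * pi / 180),
                     spec$aperture_diameter / 2)
  structure(list(x = w$x, y = w$y, current_speeds = sp, current_directions = dr),
            class = "dot_field")
}

#' Generate one RDK interval
#'
#' Initialises a dot field and applies `n_updates - 1` positional
#' updates, recording every image and every per-update speed/direction
#' draw. With `positions = FALSE` only the draws are generated (the
#' kinematic state is skipped), which is sufficient for sample-based
#' model observers and much faster for large simulations.
#'
#' @inheritParams advance
#' @param seed optional integer seed.
#' @param positions keep per-image dot positions?
#' @return an object of class `frame_sequence`: list with `x`, `y`
#'   (`n_updates x n_dots` matrices, or `NULL`), `speeds`, `directions`
#'   (`(n_updates - 1) x n_dots` matrices of per-update draws), `spec`,
#'   `seed`, and `provenance` (deparsed sources).
#' @export
generate_interval <- function(spec = stimulus_spec(), speed_source, direction_source,
                              seed = NULL, positions = TRUE) {
  maybe_seed(seed)
  n <- spec$n_dots
  nt <- spec$n_updates - 1L
  speeds <- matrix(NA_real_, nrow = max(nt, 0L), ncol = n)
  dirs <- matrix(NA_real_, nrow = max(nt, 0L), ncol = n)
  if (positions) {
    xs <- matrix(NA_real_, nrow = spec$n_updates, ncol = n)
    ys <- xs
    field <- init_dot_field(spec)
    xs[1L, ] <- field$x; ys[1L, ] <- field$y
    if (nt > 0L) for (i in seq_len(nt)) {
      field <- advance(field, speed_source, direction_source, spec)
      xs[i + 1L, ] <- field$x; ys[i + 1L, ] <- field$y
      speeds[i, ] <- field$current_speeds
      dirs[i, ] <- field$current_directions
    }
  } else {
    xs <- NULL; ys <- NULL
    if (nt > 0L) for (i in seq_len(nt)) {
      speeds[i, ] <- draw_source(speed_source, n)
      dirs[i, ] <- draw_source(direction_source, n)
    }
  }
  prov <- function(s) if (is_discrete_distribution(s)) {
    paste0(s$kind, "-dist[", s$range_lo, ",", s$range_hi, "]")
  } else paste0("fixed:", signif(s, 6))
  structure(list(x = xs, y = ys, speeds = speeds, directions = dirs, spec = spec,
                 seed = seed,
                 provenance = c(speed = prov(speed_source),
                                direction = prov(direction_source))),
            class = "frame_sequence")
}

#' Rasterize a dot field to a luminance image
#'
#' Renders dark dots of the configured diameter on the uniform
#' background, sampling the aperture bounding square at
#' `pixels_per_deg`. Deterministic; intended for visual inspection and
#' image-based observers, not for display-fidelity claims.
#'
#' @param field a `dot_field`.
#' @param pixels_per_deg raster resolution (the hardware pixel pitch of
#'   1.35 arc min corresponds to about 44.4 px/deg).
#' @param spec a [stimulus_spec()] supplying luminances and geometry.
#' @return a numeric matrix of luminances (cd/m^2), rows = y (top to
#'   bottom), columns = x.
#' @export
rasterize <- function(field, pixels_per_deg = 44.4, spec = stimulus_spec()) {
  stopifnot(pixels_per_deg > 0)
  half <- spec$aperture_diameter / 2
  npx <- ceiling(spec$aperture_diameter * pixels_per_deg)
  cent <- (seq_len(npx) - 0.5) / pixels_per_deg - half  # pixel-centre coords, deg
  img <- matrix(spec$background_luminance, nrow = npx, ncol = npx)
  rdot <- spec$dot_diameter / 2
  rpix <- ceiling(rdot * pixels_per_deg) + 1L
  for (k in seq_along(field$x)) {
    cx <- field$x[k]; cy <- field$y[k]
    ix <- which(abs(cent - cx) <= (rpix + 1) / pixels_per_deg)
    iy <- which(abs(cent - cy) <= (rpix + 1) / pixels_per_deg)
    if (!length(ix) || !length(iy)) next
    dx2 <- (cent[ix] - cx)^2
    dy2 <- (cent[iy] - cy)^2
    hit <- outer(dy2, dx2, "+") <= rdot^2
    img[iy, ix][hit] <- spec$dot_luminance
  }
  img
}

#' Write a frame sequence as a trajectory CSV
#'
#' One row per dot per image: `trial_id, interval_index, update_index,
#' dot_id, x_deg, y_deg, speed_deg_per_s, direction_deg`. The speed and
#' direction on each row are the draws that moved the dot *out of* that
#' image; the final image has none and carries `NA`. Unit documentation
#' is written as `#`-prefixed header comments.
#'
#' @param seq a `frame_sequence` generated with `positions = TRUE`.
#' @param path output file path.
#' @param trial_id,interval_index identifiers recorded on every row.
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(seq, path, trial_id = 1L, interval_index = 1L) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (is.null(seq$x)) stop("write_trajectory_csv(): sequence has no positions")
  nu <- nrow(seq$x); nd <- ncol(seq$x)
  pad <- rbind(seq$speeds, NA_real_)
  padd <- rbind(seq$directions, NA_real_)
  df <- data.frame(trial_id = trial_id, interval_index = interval_index,
                   update_index = rep(seq_len(nu), times = nd),
                   dot_id = rep(seq_len(nd), each = nu),
                   x_deg = as.vector(seq$x), y_deg = as.vector(seq$y),
                   speed_deg_per_s = as.vector(pad),
                   direction_deg = as.vector(padd))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# RDK dot trajectory: positions in deg relative to aperture centre,",
               "# speeds in deg/s, directions in deg (0 = rightward, CCW positive).",
               "# speed/direction on a row are the draws leaving that image (NA on the last)."),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path file path.
#' @return a data frame with the documented columns.
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
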