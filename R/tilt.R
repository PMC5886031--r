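# Exponential tilting: the maximum-entropy reweighting of a fixed band
# grid that moves its mean to a target value. Used wherever a comparison
# band must hit a prescribed local mean (mean-distance and
# constant-distance constructions).

#' Solve for exponential-tilt weights with a target mean
#'
#' Given a band of support points `x`, finds weights of the form
#' `w_i ∝ exp(lambda * x_i)` whose weighted mean equals `target_mean`.
#' This is the maximum-entropy (minimally informative) distribution on
#' the band satisfying the mean constraint; `lambda = 0` (uniform
#' weights) is returned exactly when the target equals the unweighted
#' band mean. The weighted mean is strictly increasing in `lambda`, so
#' `lambda` is found by expanding a bracket (doubling from `|lambda| = 1`)
#' and root-finding to 1e-12.
#'
#' @param band numeric vector of support points (need not be sorted).
#' @param target_mean desired weighted mean; must lie strictly inside
#'   `(min(band), max(band))`.
#' @param tolerance acceptable error on the achieved mean (stimulus units).
#' @return a list with `weights` (summing to 1), `lambda`, and
#'   `achieved_mean`.
#' @examples
#' s <- solve_band_tilt(seq(0.4, 8.4, by = 1), 6)
#' sum(s$weights * seq(0.4, 8.4, by = 1))   # 6
#' @export
solve_band_tilt <- function(band, target_mean, tolerance = 1e-6) {
  stopifnot(is.numeric(band), length(band) >= 1L, is.numeric(target_mean))
  if (length(band) == 1L) {
    if (abs(band - target_mean) > tolerance) {
      stop("solve_band_tilt(): single-point band at ", band,
           " cannot have mean ", target_mean)
    }
    return(list(weights = 1, lambda = 0, achieved_mean = band))
  }
  lo <- min(band); hi <- max(band)
  if (target_mean <= lo + 1e-12 || target_mean >= hi - 1e-12) {
    stop("solve_band_tilt(): target mean ", target_mean,
         " is not strictly inside the band (", lo, ", ", hi, ")")
  }
  xbar <- mean(band)
  if (abs(target_mean - xbar) <= 1e-12 * max(1, abs(xbar))) {
    return(list(weights = rep.int(1 / length(band), length(band)),
                lambda = 0, achieved_mean = xbar))
  }
  # Centre the support for numerical stability; lambda is unchanged.
  xc <- band - xbar
  tilted_mean <- function(lambda) {
    e <- exp(lambda * xc - max(lambda * xc))
    sum(band * e) / sum(e)
  }
  f <- function(lambda) tilted_mean(lambda) - target_mean
  sgn <- if (target_mean > xbar) 1 else -1
  hi_l <- sgn
  it <- 0L
  while (sgn * f(hi_l) < 0 && it < 200L) {
    hi_l <- hi_l * 2
    it <- it + 1L
  }
  if (sgn * f(hi_l) < 0) {
    stop("solve_band_tilt(): failed to bracket lambda for target mean ", target_mean)
  }
  root <- stats::uniroot(f, lower = min(0, hi_l), upper = max(0, hi_l),
                         tol = 1e-12)$root
  e <- exp(root * xc - max(root * xc))
  w <- e / sum(e)
  achieved <- sum(band * w)
  if (abs(achieved - target_mean) > tolerance) {
    stop("solve_band_tilt(): achieved mean ", achieved, " misses target ",
         target_mean, " beyond tolerance ", tolerance)
  }
  list(weights = w, lambda = root, achieved_mean = achieved)
}
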