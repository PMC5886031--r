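# Small shared helpers: unit conversions, seed derivation, guarded sampling.

#' Convert between arc minutes and degrees
#'
#' Displacement levels for the Dmax task are specified in arc minutes
#' (1 deg = 60 arc min); dot kinematics are computed in degrees.
#'
#' @param x numeric vector of arc minutes (or degrees).
#' @return numeric vector in the other unit.
#' @export
arcmin_to_deg <- function(x) x / 60

#' @rdname arcmin_to_deg
#' @export
deg_to_arcmin <- function(x) x * 60

#' Derive a component seed from a master seed
#'
#' A single master seed is used to spawn deterministic sub-seeds for
#' independent components (distribution sampling, trial scheduling,
#' observer noise), so any component can be re-run in isolation and
#' reproduce its part of a session. The derivation is a fixed integer
#' hash of the master seed and a stream label; it stays below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stream character label for the component stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 97861
  as.integer((((abs(master) %% 97861) * 131071 + h * 2377 + 1) %% 2147483646) + 1)
}

# sample() treats a length-1 numeric first argument as 1:n; guard against
# that when drawing from degenerate single-point supports.
sample_values <- function(values, n, prob = NULL) {
  if (length(values) == 1L) return(rep.int(values, n))
  sample(values, n, replace = TRUE, prob = prob)
}

# Set the RNG only when a seed is supplied; otherwise draw from the
# caller's stream so nested calls stay reproducible under one master seed.
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
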