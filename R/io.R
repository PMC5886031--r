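# Run configuration, output writing, and fixture generation.

run_config_fields <- c("experiment", "variant", "trial_speed",
                       "trials_per_condition", "seed", "observer",
                       "stimulus", "distribution", "output_dir")

#' Load and validate a run configuration
#'
#' Reads a JSON experiment configuration, rejects unknown keys, and
#' fills defaults (the printed stimulus constants, 280 trials per
#' condition, the guessing observer). A persisted configuration re-runs
#' to identical outputs via its `seed`.
#'
#' @param path path to a JSON file, or a raw JSON string via `json`.
#' @param json JSON text (alternative to `path`).
#' @return an object of class `run_config`: a validated list with
#'   fields `experiment`, `variant`, `trial_speed`,
#'   `trials_per_condition`, `seed`, `observer` (name + params),
#'   `stimulus` (a [stimulus_spec()]), `distribution` (parameter
#'   overrides), `output_dir`.
#' @export
load_config <- function(path = NULL, json = NULL) {
  obj <- jsonlite::fromJSON(if (is.null(json)) path else json, simplifyVector = TRUE)
  unknown <- setdiff(names(obj), run_config_fields)
  if (length(unknown)) {
    stop("load_config(): unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(obj$experiment)) stop("load_config(): 'experiment' is required")
  exp_id <- obj$experiment
  if (!identical(exp_id, "dmax")) {
    exp_id <- as.integer(exp_id)
    if (is.na(exp_id) || exp_id < 1L || exp_id > 4L) {
      stop("load_config(): 'experiment' must be 1-4 or \"dmax\"")
    }
  }
  trials <- obj$trials_per_condition %||% 280L
  if (trials < 1) stop("load_config(): 'trials_per_condition' must be positive")
  spec_args <- obj$stimulus %||% list()
  bad <- setdiff(names(spec_args), names(formals(stimulus_spec)))
  if (length(bad)) {
    stop("load_config(): unknown stimulus field(s): ", paste(bad, collapse = ", "))
  }
  spec <- do.call(stimulus_spec, spec_args)  # stimulus_spec() validates values
  observer <- obj$observer %||% list(name = "guess")
  if (is.character(observer)) observer <- list(name = observer)
  structure(list(experiment = exp_id, variant = obj$variant,
                 trial_speed = obj$trial_speed,
                 trials_per_condition = as.integer(trials),
                 seed = obj$seed %||% 1L, observer = observer,
                 stimulus = spec, distribution = obj$distribution %||% list(),
                 output_dir = obj$output_dir %||% "."),
            class = "run_config")
}

#' Save a run configuration as JSON
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- config
  class(obj) <- NULL
  obj$stimulus <- unclass(obj$stimulus)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Instantiate the observer named in a configuration
#'
#' @param observer a list with `name` (one of `guess`, `gap-oracle`,
#'   `noisy-speed`, `direction-gap`, `dmax`) and optional `params`.
#' @return an [observer_model()].
#' @export
make_observer <- function(observer) {
  p <- observer$params %||% list()
  switch(observer$name,
         guess = observer_guessing(),
         `gap-oracle` = observer_speed_gap(0),
         `noisy-speed` = observer_speed_gap(p$noise_fraction %||% 0.15),
         `direction-gap` = do.call(observer_direction_gap, p),
         dmax = do.call(observer_dmax, p),
         stop("make_observer(): unknown observer '", observer$name, "'"))
}

#' Run a configured experiment end to end
#'
#' Builds the conditions, instantiates the observer, and runs the
#' session; the whole run is determined by the configuration (including
#' its master seed).
#'
#' @param config a `run_config` from [load_config()].
#' @return a `session_log`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  conds <- experiment_conditions(config$experiment, variant = config$variant,
                                 trial_speed = config$trial_speed,
                                 params = config$distribution)
  run_session(conds, make_observer(config$observer),
              n_trials_per_condition = config$trials_per_condition,
              spec = config$stimulus, seed = config$seed)
}

#' Write session outputs with metadata
#'
#' Writes the session log and its performance table as CSV files, and a
#' JSON metadata file (package version, seed, observer, config hash)
#' alongside them.
#'
#' @param log a `session_log`.
#' @param table optional `performance_table`; computed from the log if
#'   missing and the log is non-empty.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param config optional `run_config` to hash into the metadata.
#' @return named character vector of the written paths.
#' @export
write_outputs <- function(log, table = NULL, dir = ".", prefix = "session",
                          config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  log_path <- file.path(dir, paste0(prefix, "_log.csv"))
  utils::write.csv(as.data.frame(log), log_path, row.names = FALSE)
  paths <- c(log = log_path)
  if (is.null(table) && nrow(log) > 0) table <- summarize_session(log)
  if (!is.null(table)) {
    tab_path <- file.path(dir, paste0(prefix, "_summary.csv"))
    utils::write.csv(as.data.frame(table), tab_path, row.names = FALSE)
    paths <- c(paths, summary = tab_path)
  }
  meta <- list(package = "rdknotch",
               version = as.character(utils::packageVersion("rdknotch")),
               seed = attr(log, "seed"), observer = attr(log, "observer"),
               n_trials = nrow(log),
               config_hash = if (is.null(config)) NULL else config_hash(config),
               written = format(Sys.time(), tz = "UTC", usetz = TRUE))
  meta_path <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, null = "null")
  c(paths, meta = meta_path)
}

# Order-stable integer hash of a serialized config; enough to detect
# that two outputs came from different configurations.
config_hash <- function(config) {
  txt <- as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                       digits = NA, force = TRUE))
  codes <- utf8ToInt(txt)
  sprintf("%08x", sum(codes * (seq_along(codes) %% 251 + 1)) %% 4294967291)
}

#' Generate the small deterministic fixtures used by the test suite
#'
#' All fixtures are built in code in well under a second: the default
#' standard distribution, a wide-notch comparison, a 3-dot / 10-image
#' trajectory, and a short guessing-observer log.
#'
#' @param seed integer seed.
#' @return a named list: `standard`, `comparison_notch19`, `trajectory`
#'   (a `frame_sequence`), `log_guessing` (a 30-trial `session_log`).
#' @export
make_fixtures <- function(seed = 1) {
  std <- build_uniform(0.4, 23.6, 1)
  cmp <- build_symmetric_notched(0.4, 23.6, 19, 1)
  tiny_spec <- stimulus_spec(n_dots = 3, aperture_diameter = 12, dot_density = NULL)
  traj <- generate_interval(tiny_spec, std, 90, seed = derive_seed(seed, "fixture-traj"))
  conds <- list(list(label = "notch_19", param = 19, standard = std, comparison = cmp))
  log <- run_session(conds, observer_guessing(), n_trials_per_condition = 30,
                     seed = derive_seed(seed, "fixture-log"))
  list(standard = std, comparison_notch19 = cmp, trajectory = traj,
       log_guessing = log)
}
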